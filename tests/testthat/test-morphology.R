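test_that("morphotype rules classify the canonical corner cases", {
  th <- morphotype_thresholds(0.7, 0.85, 0.6, 0.8)
  expect_identical(classify_morphotype(0.95, 0.2, th), "ameboid")
  expect_identical(classify_morphotype(0.5, 0.95, th), "ramified")
  expect_identical(classify_morphotype(0.95, 0.95, th), "ambiguous")
  expect_identical(classify_morphotype(0.78, 0.7, th), "rod")
  # partition: every point in [0,1]^2 receives exactly one class
  g <- expand.grid(s = seq(0, 1, 0.05), e = seq(0, 1, 0.05))
  cls <- classify_morphotype(g$s, g$e, th)
  expect_true(all(cls %in% c("ramified", "rod", "ameboid", "ambiguous")))
})

test_that("tertile-derived thresholds follow the DMSO population", {
  set.seed(3)
  dmso <- data.frame(solidity = runif(600), eccentricity = runif(600))
  th <- morphotype_thresholds(dmso_cells = dmso)
  expect_identical(th$derivation, "dmso_tertiles")
  expect_lt(abs(th$solidity_low - 1 / 3), 0.08)
  expect_lt(abs(th$eccentricity_high - 2 / 3), 0.08)
  expect_error(morphotype_thresholds(0.8, 0.7), "low < high")
  expect_error(morphotype_thresholds(0.7, 1.2), "\\[0, 1\\]")
})

test_that("compound phenotypes aggregate field means and cell fractions", {
  wells <- data.frame(
    plate = "P01", well = c("A01", "A02", "B01", "B02"),
    role = "compound", compound = rep(c("c1", "c2"), each = 2),
    phagocytic_index = c(1.0, 1.2, 0.4, 0.6),
    mean_solidity = c(0.5, 0.6, 0.9, 0.8),
    mean_eccentricity = c(0.9, 0.8, 0.3, 0.4),
    mean_iba1 = c(0.4, 0.6, 0.7, 0.9),
    excluded = FALSE, stringsAsFactors = FALSE)
  cells <- data.frame(
    compound = rep(c("c1", "c2"), each = 4),
    solidity = c(rep(0.5, 4), rep(0.95, 4)),
    eccentricity = c(rep(0.9, 4), rep(0.2, 4)))
  ph <- compound_phenotypes(wells, cells)
  expect_equal(ph$phagocytic_index, c(1.1, 0.5))
  expect_equal(ph$mean_solidity, c(0.55, 0.85))
  expect_equal(ph$frac_ramified, c(1, 0))
  expect_equal(ph$frac_ameboid, c(0, 1))
  expect_equal(ph$frac_ramified + ph$frac_rod + ph$frac_ameboid +
                 ph$frac_ambiguous, c(1, 1), tolerance = 1e-9)
  # identical compounds give identical phenotypes
  w2 <- wells; w2$compound <- rep(c("c1", "c3"), each = 2)
  w2$phagocytic_index <- rep(c(1.0, 1.2), 2)
  w2$mean_solidity <- rep(c(0.5, 0.6), 2)
  w2$mean_eccentricity <- rep(c(0.9, 0.8), 2)
  w2$mean_iba1 <- rep(c(0.4, 0.6), 2)
  ph2 <- compound_phenotypes(w2)
  expect_equal(ph2[1, -1], ph2[2, -1], ignore_attr = TRUE)
  expect_false(any(ph2$fractions_defined))
})

test_that("feature correlation matches closed-form arithmetic and is symmetric", {
  ph <- data.frame(a = c(1, 2, 3), b = c(2, 4, 5))
  fc <- feature_correlation(ph, "a", "b")
  expect_equal(round(fc$r, 4), 0.982)
  expect_equal(feature_correlation(ph, "b", "a")$r, fc$r)
  # exact anticorrelation
  ph2 <- data.frame(x = 1:5, y = -(1:5))
  expect_equal(feature_correlation(ph2, "x", "y")$r, -1)
  # affine rescaling leaves |r| unchanged, sign follows the slope
  ph3 <- data.frame(x = rnorm(20), y = rnorm(20))
  r0 <- feature_correlation(ph3, "x", "y")$r
  ph3$y2 <- -3 * ph3$y + 7
  expect_equal(feature_correlation(ph3, "x", "y2")$r, -r0,
               tolerance = 1e-12)
  expect_error(feature_correlation(data.frame(x = c(1, 1, 1), y = 1:3),
                                   "x", "y"), "zero variance")
})

test_that("correlation p-values are uniform under independence", {
  set.seed(12)
  ps <- replicate(300, {
    ph <- data.frame(x = rnorm(30), y = rnorm(30))
    feature_correlation(ph, "x", "y")$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("planted solidity-eccentricity anticorrelation is recovered", {
  cfg <- screen_sim_config(n_compounds = 100L, fields_per_well = 6L,
                           morph_cor = -0.9, seed = 17L)
  sim <- simulate_screen(cfg)
  ph <- compound_phenotypes(summarize_wells(sim$fields))
  fc <- feature_correlation(ph, "mean_solidity", "mean_eccentricity")
  expect_lt(abs(fc$r - (-0.9)), 0.05)
})

test_that("a strong eccentricity-shifting compound ranks highest", {
  msm <- default_morph_shift_model()
  msm$d_eccentricity[msm$class == "activator"] <- 0.2
  msm$d_iba1[msm$class == "activator"] <- -0.15
  cfg <- screen_sim_config(n_compounds = 50L, fields_per_well = 6L,
                           effect_classes = c("activator",
                                              rep("null", 49)),
                           morph_shift_model = msm, morph_sd = 0.03,
                           seed = 19L)
  sim <- simulate_screen(cfg)
  ph <- compound_phenotypes(summarize_wells(sim$fields))
  expect_identical(ph$compound[which.max(ph$mean_eccentricity)],
                   sim$truth$compound[1])
})

test_that("phenotype PCA has orthonormal loadings and reconstructs", {
  set.seed(14)
  ph <- data.frame(compound = sprintf("c%02d", 1:40),
                   phagocytic_index = rnorm(40),
                   mean_solidity = rnorm(40),
                   mean_eccentricity = rnorm(40),
                   mean_iba1 = rnorm(40))
  p <- phenotype_pca(ph)
  expect_equal(crossprod(p$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  # reconstruction of the standardized matrix
  xs <- scale(as.matrix(ph[, -1]))
  expect_equal(max(abs(p$scores %*% t(p$loadings) - xs)), 0,
               tolerance = 1e-10)
  # sign convention: largest-magnitude loading positive
  for (j in 1:4) {
    v <- p$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("PCA exposes forced anticorrelation and degeneracy", {
  set.seed(15)
  s <- runif(30)
  ph <- data.frame(mean_solidity = s, mean_eccentricity = 1 - s)
  p <- phenotype_pca(ph, features = c("mean_solidity",
                                      "mean_eccentricity"))
  expect_equal(p$variance_fraction[1], 1, tolerance = 1e-12)
  # biplot arrows (loadings weighted by component scale) are antiparallel
  v <- sweep(p$loadings, 2, sqrt(p$variance_fraction), "*")
  cosang <- sum(v[1, ] * v[2, ]) /
    sqrt(sum(v[1, ]^2) * sum(v[2, ]^2))
  expect_lte(cosang, -0.99)
  expect_error(phenotype_pca(data.frame(a = rnorm(10), b = rep(1, 10)),
                             features = c("a", "b")), "b")
})
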