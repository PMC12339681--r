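test_that("size factors reproduce median-of-ratios arithmetic", {
  m <- matrix(c(10, 20, 20, 40, 30, 60), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("w1", "w2")))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(sqrt(0.5), sqrt(2)), tolerance = 1e-12)
  # doubling one well doubles its factor (after renormalization the
  # ratio of factors doubles)
  m2 <- m; m2[, 2] <- m2[, 2] * 2
  sf2 <- size_factors(m2)
  expect_equal(unname(sf2[2] / sf2[1]), 2 * unname(sf[2] / sf[1]),
               tolerance = 1e-12)
  # identical wells: all factors 1
  m3 <- cbind(w1 = c(5, 8, 13), w2 = c(5, 8, 13), w3 = c(5, 8, 13))
  expect_equal(unname(size_factors(m3)), rep(1, 3))
  # gene order is irrelevant
  expect_equal(size_factors(m[c(3, 1, 2), ]), sf)
  # fallback when no gene is nonzero everywhere
  m4 <- matrix(c(0, 10, 10, 0), 2, 2,
               dimnames = list(c("g1", "g2"), c("w1", "w2")))
  expect_warning(size_factors(m4), "positive-count")
})

test_that("independent cross-check: size factors agree with DESeq2", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_counts(counts_sim_config(n_genes = 500L,
                                           n_compounds = 2L, seed = 31L))
  ours <- size_factors(sim$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts)
  # DESeq2 leaves its factors unnormalized; compare after rescaling both
  # to geometric mean 1
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})

test_that("BH adjustment reproduces step-up arithmetic", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(23)
  p <- runif(200)
  expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the NB test is calibrated under the null", {
  sim <- simulate_counts(counts_sim_config(n_genes = 3000L,
                                           n_compounds = 1L, seed = 11L))
  de <- nb_test(sim$counts,
                sim$meta$well[sim$meta$role == "compound"],
                sim$meta$well[sim$meta$role == "dmso"][1:4])
  expect_identical(nrow(de), 3000L)
  frac <- mean(de$p_value < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  expect_true(all(de$adjusted_p >= de$p_value))
  expect_true(all(de$p_value >= 0 & de$p_value <= 1))
})

test_that("a planted four-fold change is estimated within half a log2 unit", {
  cfg <- counts_sim_config(n_genes = 2000L, n_compounds = 1L,
                           active = TRUE, n_de_genes = 300L,
                           de_lfc = 2, dispersion = 0.1, seed = 5L)
  sim <- simulate_counts(cfg)
  de <- nb_test(sim$counts,
                sim$meta$well[sim$meta$role == "compound"],
                sim$meta$well[sim$meta$role == "dmso"][1:4])
  tg <- sim$truth$de_genes
  est <- de$log2_fold_change[match(tg$gene, de$gene)]
  # well-expressed planted genes recover the effect size: the average
  # estimate sits within half a log2 unit of the truth in each direction
  mu <- de$mean_expression[match(tg$gene, de$gene)]
  strong <- mu > 50
  expect_gt(sum(strong), 80L)
  up <- strong & tg$log2fc > 0
  dn <- strong & tg$log2fc < 0
  expect_lt(abs(mean(est[up]) - 2), 0.5)
  expect_lt(abs(mean(est[dn]) + 2), 0.5)
  expect_lt(mean(abs(est[strong] - tg$log2fc[strong])), 0.5)
})

test_that("the NB test is symmetric and handles all-zero genes", {
  sim <- simulate_counts(counts_sim_config(n_genes = 300L,
                                           n_compounds = 1L, seed = 41L))
  counts <- sim$counts
  counts[7, ] <- 0L
  g1 <- sim$meta$well[sim$meta$role == "compound"]
  g2 <- sim$meta$well[sim$meta$role == "dmso"][1:4]
  sf <- size_factors(counts + 1L)  # avoid refitting factors per direction
  a <- nb_test(counts, g1, g2, sf = sf)
  b <- nb_test(counts, g2, g1, sf = sf)
  expect_equal(a$log2_fold_change, -b$log2_fold_change, tolerance = 1e-10)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
  expect_equal(a$p_value[7], 1)
  expect_equal(a$log2_fold_change[7], 0)
  expect_error(nb_test(counts, g1, c(g2, g1[1])), "overlap")
  expect_error(nb_test(counts, g1[1], g2), ">= 2")
})

test_that("DEG counting uses strict thresholds and is monotone", {
  de <- data.frame(gene = paste0("g", 1:4),
                   log2_fold_change = c(2, 1, -3, 0.5),
                   p_value = c(0.001, 0.001, 0.02, 0.5),
                   adjusted_p = c(0.01, 0.01, 0.1, 0.9))
  expect_identical(count_deg(de), 1L)  # g3 at padj exactly 0.1 excluded;
                                       # g2 at |lfc| exactly 1 excluded
  expect_identical(count_deg(de[0, ]), 0L)
  # monotone in both thresholds
  expect_lte(count_deg(de, padj_max = 0.05), count_deg(de, padj_max = 0.2))
  expect_lte(count_deg(de, lfc_min = 2), count_deg(de, lfc_min = 0.1))
})

test_that("the DMSO null uses nearest-rank percentiles and fixed seeds", {
  x <- c(0, 0, 1, 1, 2, 2, 3, 3, 4, 20)
  expect_identical(phagoscreen:::nearest_rank_percentile(x, 0.95), 20)
  expect_identical(phagoscreen:::nearest_rank_percentile(x, 0.5), 2)
  sim <- simulate_counts(counts_sim_config(n_genes = 500L,
                                           n_compounds = 1L, seed = 3L))
  dmso <- sim$meta$well[sim$meta$role == "dmso"]
  n1 <- dmso_null(sim$counts, dmso, group_size = 4L, n_draws = 10L,
                  seed = 99L)
  n2 <- dmso_null(sim$counts, dmso, group_size = 4L, n_draws = 10L,
                  seed = 99L)
  expect_identical(n1$null_deg_counts, n2$null_deg_counts)
  expect_error(dmso_null(sim$counts, dmso[1:5], group_size = 3L),
               "2 \\* group_size")
})

test_that("RNA-activity calls are strict and planted actives are found", {
  null <- list(null_95th_percentile = 18L)
  expect_true(call_rna_active("a", 30L, null)$active)
  expect_false(call_rna_active("b", 18L, null)$active)
  cfg <- counts_sim_config(n_genes = 1500L, n_compounds = 3L,
                           active = c(TRUE, FALSE, FALSE),
                           n_de_genes = 300L, de_lfc = 2, seed = 7L)
  sim <- simulate_counts(cfg)
  out <- rna_activity_pipeline(sim$counts, sim$meta, n_draws = 30L,
                               seed = 2L)
  expect_true(out$calls$active[out$calls$compound == "cmpd001"])
  expect_false(any(out$calls$active[out$calls$compound != "cmpd001"]))
})

test_that("hypergeometric enrichment matches the combinatorial count", {
  uni <- paste0("g", 1:20)
  res <- ora_enrichment(uni[1:5], uni[1:5], uni)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_identical(res$overlap, 5L)
  # zero overlap with tiny sets: p near 1
  expect_gt(ora_enrichment(uni[1:2], uni[19:20], uni)$p, 0.7)
  # DEG set equal to the universe: p = 1
  expect_equal(ora_enrichment(uni, uni[1:6], uni)$p, 1)
  expect_error(ora_enrichment("x", uni[1:2], uni), "subsets")
  expect_error(ora_enrichment("g1", "g1", character(0)), "empty")
})
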