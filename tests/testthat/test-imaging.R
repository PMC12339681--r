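test_that("rendering a field with no cells gives a blank mask", {
  spec <- field_render_spec(width = 64, height = 64, noise_sd = 0)
  rf <- render_field(spec)
  expect_true(all(rf$cell_mask == 0L))
  expect_identical(dim(rf$image), c(64L, 64L, 3L))
  expect_true(all(abs(rf$image - 0.05) < 1e-12))
})

test_that("disjoint ellipses produce exactly one label each", {
  rf <- render_field(disk_field(n = 5L, puncta = 0L))
  expect_identical(sort(unique(as.integer(rf$cell_mask[rf$cell_mask > 0]))),
                   1:5)
})

test_that("excessive cell overlap is rejected", {
  spec <- field_render_spec(width = 100, height = 100,
                            cells = data.frame(x = c(50, 55), y = 50,
                                               a = 20, b = 20, theta = 0,
                                               iba1 = 0.8),
                            overlap_cap = 0.05)
  expect_error(render_field(spec), "overlap")
})

test_that("shape features match analytic values for disk and ellipse", {
  disk <- render_field(field_render_spec(width = 128, height = 128,
    cells = data.frame(x = 64, y = 64, a = 30, b = 30, theta = 0,
                       iba1 = 0.8), noise_sd = 0))
  fd <- shape_features(disk$cell_mask)
  expect_lt(abs(fd$solidity - 1), 0.02)
  expect_lte(fd$eccentricity, 0.1)

  # 2:1 ellipse: eccentricity sqrt(1 - (b/a)^2) = 0.8660
  for (th in c(0, 0.4, pi / 4)) {
    ell <- render_field(field_render_spec(width = 256, height = 256,
      cells = data.frame(x = 128, y = 128, a = 60, b = 30, theta = th,
                         iba1 = 0.8), noise_sd = 0))
    fe <- shape_features(ell$cell_mask)
    expect_lt(abs(fe$eccentricity - sqrt(1 - 0.25)), 0.02)
    expect_lt(abs(fe$solidity - 1), 0.02)
  }
})

test_that("plus-sign solidity matches the hull-rasterization oracle", {
  m <- matrix(0L, 40, 40)
  m[16:24, 10:30] <- 1L
  m[10:30, 16:24] <- 1L
  sf <- shape_features(m)
  oracle <- sum(m) / hull_pixel_oracle(m)
  expect_lt(abs(sf$solidity - oracle), 0.02)
  expect_lt(sf$solidity, 0.9)  # a cross is far from convex
})

test_that("solidity and eccentricity are robust to rotation and scale", {
  base <- render_field(field_render_spec(width = 300, height = 300,
    cells = data.frame(x = 150, y = 150, a = 50, b = 25, theta = 0,
                       iba1 = 0.8), noise_sd = 0))
  rot <- render_field(field_render_spec(width = 300, height = 300,
    cells = data.frame(x = 150, y = 150, a = 50, b = 25, theta = pi / 4,
                       iba1 = 0.8), noise_sd = 0))
  up <- render_field(field_render_spec(width = 300, height = 300,
    cells = data.frame(x = 150, y = 150, a = 100, b = 50, theta = 0,
                       iba1 = 0.8), noise_sd = 0))
  f0 <- shape_features(base$cell_mask)
  fr <- shape_features(rot$cell_mask)
  fu <- shape_features(up$cell_mask)
  expect_lt(abs(f0$eccentricity - fr$eccentricity), 0.05)
  expect_lt(abs(f0$solidity - fr$solidity), 0.05)
  expect_lt(abs(f0$solidity - fu$solidity), 0.02)
})

test_that("segmentation recovers disjoint cells with high overlap", {
  rf <- render_field(disk_field(n = 5L, puncta = 0L))
  lab <- segment_cells(rf$image[, , 1], rf$image[, , 2])
  expect_identical(max(lab), 5L)
  for (i in 1:5) {
    gt <- rf$cell_mask == i
    jac <- max(vapply(seq_len(max(lab)), function(j)
      sum(gt & lab == j) / sum(gt | lab == j), numeric(1)))
    expect_gte(jac, 0.9)
  }
})

test_that("seeded watershed splits touching cells with separate nuclei", {
  spec <- field_render_spec(width = 200, height = 200,
    cells = data.frame(x = c(80, 122), y = 100, a = 22, b = 20,
                       theta = 0, iba1 = 0.8),
    noise_sd = 0.005, overlap_cap = 0.2)
  rf <- render_field(spec)
  lab <- segment_cells(rf$image[, , 1], rf$image[, , 2])
  expect_identical(max(lab), 2L)
})

test_that("segmentation validates inputs and handles blank channels", {
  expect_error(segment_cells(matrix(0, 4, 4), matrix(0, 5, 5)),
               "identical shape")
  lab <- segment_cells(matrix(0, 32, 32), matrix(0, 32, 32))
  expect_true(all(lab == 0L))
})

test_that("synaptosome area counts only in-cell above-threshold pixels", {
  # puncta entirely outside cells contribute nothing
  spec_out <- field_render_spec(width = 256, height = 256,
    cells = data.frame(x = 64, y = 64, a = 25, b = 25, theta = 0,
                       iba1 = 0.8),
    puncta_inside = 0L, puncta_outside = 8L, noise_sd = 0, seed = 3L)
  rf <- render_field(spec_out)
  expect_identical(synaptosome_area(rf$image[, , 3], rf$cell_mask,
                                    imaging_params(phrodo_threshold = 0.3)),
                   0L)
  # blank channel
  expect_identical(synaptosome_area(matrix(0, 64, 64),
                                    matrix(1L, 64, 64),
                                    imaging_params(phrodo_threshold = 0.3)),
                   0L)
  # one 5-px-radius punctum inside a large cell
  spec_in <- field_render_spec(width = 128, height = 128,
    cells = data.frame(x = 64, y = 64, a = 40, b = 40, theta = 0,
                       iba1 = 0.8),
    puncta_inside = 1L, puncta_radius = 5, noise_sd = 0, seed = 2L)
  rf2 <- render_field(spec_in)
  a <- synaptosome_area(rf2$image[, , 3], rf2$cell_mask,
                        imaging_params(phrodo_threshold = 0.3))
  expect_lt(abs(a - rf2$puncta$area_px), 0.15 * rf2$puncta$area_px + 1)
})

test_that("measure_field composes the stage and flags empty fields", {
  rf <- render_field(disk_field(n = 5L, puncta = 10L))
  mf <- measure_field(list(nuclei = rf$image[, , 1],
                           iba1 = rf$image[, , 2],
                           phrodo = rf$image[, , 3]))
  expect_identical(mf$summary$cell_count, 5L)
  expect_identical(mf$summary$qc_flag, "none")
  truth_area <- sum(rf$puncta_mask > 0 & rf$cell_mask > 0)
  expect_lt(abs(mf$summary$synaptosome_area - truth_area),
            0.10 * truth_area)
  expect_identical(nrow(mf$cells), 5L)

  blank <- matrix(0, 64, 64)
  mfe <- measure_field(list(nuclei = blank, iba1 = blank, phrodo = blank))
  expect_identical(mfe$summary$qc_flag, "empty")
  expect_identical(mfe$summary$cell_count, 0L)
})
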