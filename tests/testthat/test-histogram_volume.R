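test_that("histogram counts are complete and span the grayvalue range", {
  v <- c(rep(10, 60), rep(100, 40))
  h <- compute_histogram(v, 32)
  expect_identical(sum(h$counts), 100L)
  expect_identical(sum(h$counts > 0), 2L)   # two delta-valued classes
  expect_equal(h$breaks[1], 10)
  expect_equal(h$breaks[length(h$breaks)], 100)
  expect_false(h$constant)
  hc <- compute_histogram(rep(5, 100), 32)
  expect_true(hc$constant)
  expect_error(compute_histogram(v, 8), "n_bins")
})

test_that("uniform noise gives approximately flat counts", {
  set.seed(5)
  h <- compute_histogram(runif(50000), 20)
  chi2 <- sum((h$counts - 2500)^2 / 2500)
  expect_lt(chi2, qchisq(0.999, df = 19))
})

test_that("fit_peaks recovers programmed two-component mixtures", {
  v <- sample_mixture(1e5, c(0.7, 0.3), c(10, 100), c(3, 3), seed = 11)
  fit <- fit_peaks(compute_histogram(v, 128), k = 2)
  expect_identical(fit$k, 2L)
  expect_equal(fit$components$weight, c(0.7, 0.3), tolerance = 0.02)
  expect_equal(fit$components$mean, c(10, 100), tolerance = 0.05)
  # AUTO also lands on an effective two-component solution
  fit_auto <- fit_peaks(compute_histogram(v, 128))
  big <- fit_auto$components$weight > 0.01
  expect_equal(sum(fit_auto$components$weight[big]), 1, tolerance = 0.02)
  expect_equal(sort(fit_auto$components$mean[big]), c(10, 100),
               tolerance = 0.5)
})

test_that("fit_peaks recovers three programmed weights within 0.03", {
  v <- sample_mixture(1e5, c(0.5, 0.3, 0.2), c(20, 60, 160), c(6, 6, 8),
                      seed = 21)
  fit <- fit_peaks(compute_histogram(v, 128), k = 3)
  expect_equal(fit$components$weight, c(0.5, 0.3, 0.2), tolerance = 0.03)
})

test_that("single-class input yields one effective component under AUTO", {
  set.seed(31)
  v <- rnorm(5e4, 60, 6)
  fit <- fit_peaks(compute_histogram(v, 64))
  expect_gte(max(fit$components$weight), 0.98)
  expect_lt(sum(fit$components$weight[fit$components$weight < max(
    fit$components$weight)]), 0.02)
  expect_error(fit_peaks(compute_histogram(rep(1, 100), 32)), "degenerate")
})

test_that("remaining ratio tracks phantom ground truth", {
  g <- small_graph()
  lv <- voxelize(g, 0.02)
  mm <- material_model()
  roi <- roi_cylinder(lv, 2.0)
  # pristine, noiseless and unblurred
  gv <- render_grayscale(lv, mm, psf_sigma = 0, noise_sd = 0)
  fit <- fit_peaks(compute_histogram(gv, 128, roi), model = mm)
  est <- remaining_volume_ratio(fit, g)
  expect_gt(est$remaining_ratio, 0.93)
  expect_lt(est$remaining_ratio, 1.07)
  expect_false(est$no_mg_component)
  # eroded to the closed-form 50% level
  d50 <- 0.11 * (1 - sqrt(0.5)) / 2
  lv50 <- apply_degradation(lv, g, degradation_state(
    erosion_depth = d50, substitution_fraction_dense = 0,
    substitution_fraction_lucent = 0, seed = 2))
  gv50 <- render_grayscale(lv50, mm, psf_sigma = 0, noise_sd = 0)
  fit50 <- fit_peaks(compute_histogram(gv50, 128, roi), model = mm)
  est50 <- remaining_volume_ratio(fit50, g)
  expect_gt(est50$remaining_ratio, 0.43)
  expect_lt(est50$remaining_ratio, 0.57)
  # fully resorbed
  lv0 <- apply_degradation(lv, g, degradation_state(
    erosion_depth = 0.06, substitution_fraction_dense = 0,
    substitution_fraction_lucent = 0, seed = 2))
  gv0 <- render_grayscale(lv0, mm, psf_sigma = 0, noise_sd = 0)
  fit0 <- fit_peaks(compute_histogram(gv0, 128, roi), model = mm)
  est0 <- suppressWarnings(remaining_volume_ratio(fit0, g))
  expect_lt(est0$remaining_ratio, 0.02)
})

test_that("estimated ratio is monotone along a degradation schedule", {
  g <- build_design(scaffold_design(n_rings = 1))
  lv <- voxelize(g, 0.02)
  mm <- material_model()
  roi <- roi_cylinder(lv, 2.0)
  ratios <- vapply(c(0, 0.01, 0.02, 0.03, 0.04), function(d) {
    lvd <- apply_degradation(lv, g, degradation_state(
      erosion_depth = d, substitution_fraction_dense = 0,
      substitution_fraction_lucent = 0, seed = 8))
    gv <- render_grayscale(lvd, mm, psf_sigma = 1, noise_sd = 10, seed = 8)
    fit <- fit_peaks(compute_histogram(gv, 128, roi), model = mm)
    remaining_volume_ratio(fit, g, attribution = "midpoint",
                           model = mm)$remaining_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) <= 0.01))
})

test_that("fit exports write CSV", {
  v <- sample_mixture(2e4, c(0.6, 0.4), c(10, 100), c(3, 3), seed = 1)
  fit <- fit_peaks(compute_histogram(v, 64), k = 2)
  td <- withr::local_tempdir()
  paths <- export_fit(fit, components_csv = file.path(td, "comp.csv"),
                      histogram_csv = file.path(td, "hist.csv"))
  expect_equal(nrow(read.csv(paths$components_csv)), 2)
  expect_equal(sum(read.csv(paths$histogram_csv)$count), 2e4)
})
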