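test_that("voxelized Mg volume matches the analytic swept volume", {
  g <- small_graph()
  lv <- voxelize(g, 0.02)
  mg_vol <- sum(lv$data == MATERIAL_CLASSES[["MG_ALLOY"]]) * lv$spacing^3
  expect_lt(abs(mg_vol / design_volume(g) - 1), 0.10)
  # straight strut: exact sampling grid, so the match is tight
  fx <- straight_strut(spacing = 0.02)
  mg_vol2 <- sum(fx$volume$data == MATERIAL_CLASSES[["MG_ALLOY"]]) * 0.02^3
  expect_lt(abs(mg_vol2 / (0.1 * 0.1 * 2) - 1), 0.03)
})

test_that("voxelize validates resolution and handles an empty graph", {
  g <- small_graph()
  expect_error(voxelize(g, spacing = 0.05), "too coarse")
  g_empty <- g
  g_empty$segments <- list()
  lv <- voxelize(g_empty, 0.02)
  expect_identical(sum(lv$data == MATERIAL_CLASSES[["MG_ALLOY"]]), 0L)
})

test_that("halving the spacing changes the Mg volume estimate by < 5%", {
  g <- build_design(scaffold_design(n_rings = 1))
  v1 <- sum(voxelize(g, 0.02)$data == 3L) * 0.02^3
  v2 <- sum(voxelize(g, 0.01)$data == 3L) * 0.01^3
  expect_lt(abs(v1 / v2 - 1), 0.05)
})

test_that("erosion matches the closed-form area fraction on straight struts", {
  fx <- straight_strut(w = 0.1, h = 0.1, spacing = 0.02)
  n0 <- sum(fx$volume$data == 3L)
  st <- degradation_state(erosion_depth = 0.02, seed = 1)
  lv2 <- apply_degradation(fx$volume, fx$graph, st)
  expect_lt(abs(sum(lv2$data == 3L) / n0 - (1 - 2 * 0.02 / 0.1)^2), 0.07)
  # rectangular cross-section
  fxr <- straight_strut(w = 0.2, h = 0.1, spacing = 0.02)
  n0r <- sum(fxr$volume$data == 3L)
  lvr <- apply_degradation(fxr$volume, fxr$graph, st)
  closed <- (1 - 2 * 0.02 / 0.2) * (1 - 2 * 0.02 / 0.1)
  expect_lt(abs(sum(lvr$data == 3L) / n0r - closed), 0.07)
})

test_that("degradation edge cases: identity, full erosion, unknown cut id", {
  fx <- straight_strut(spacing = 0.02)
  st0 <- degradation_state(erosion_depth = 0, seed = 3)
  expect_identical(apply_degradation(fx$volume, fx$graph, st0)$data,
                   fx$volume$data)
  st_full <- degradation_state(erosion_depth = 0.05, seed = 3)
  expect_identical(sum(apply_degradation(fx$volume, fx$graph,
                                         st_full)$data == 3L), 0L)
  st_bad <- degradation_state(cut_segment_ids = 99L)
  expect_error(apply_degradation(fx$volume, fx$graph, st_bad),
               "unknown segment id")
})

test_that("degradation is monotone in depth and conserves the voxel grid", {
  g <- small_graph()
  lv <- voxelize(g, 0.02)
  prev <- lv$data == 3L
  for (d in c(0.01, 0.02, 0.03)) {
    out <- apply_degradation(lv, g, degradation_state(erosion_depth = d,
                                                      seed = 9))
    cur <- out$data == 3L
    expect_true(all(!cur | prev))  # Mg set shrinks
    expect_identical(dim(out$data), dim(lv$data))
    expect_identical(length(out$data), length(lv$data))
    prev <- cur
  }
})

test_that("substitution draw is seeded and forms contiguous precipitates", {
  g <- small_graph()
  lv <- voxelize(g, 0.02)
  st <- function(seed) degradation_state(erosion_depth = 0.02, seed = seed)
  a <- apply_degradation(lv, g, st(5))
  b <- apply_degradation(lv, g, st(5))
  c <- apply_degradation(lv, g, st(6))
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
  # substitution fractions approximately honoured over the eroded shell
  shell <- lv$data == 3L & a$data != 3L
  n_shell <- sum(shell)
  expect_gt(n_shell, 1000)
  f_dense <- sum(a$data[shell] == MATERIAL_CLASSES[["PRODUCT_DENSE"]]) / n_shell
  expect_lt(abs(f_dense - 0.5), 0.1)
})

test_that("rendering is exact without blur/noise and seeded with noise", {
  g <- build_design(scaffold_design(n_rings = 1))
  lv <- voxelize(g, 0.02)
  mm <- material_model()
  gv0 <- render_grayscale(lv, mm, psf_sigma = 0, noise_sd = 0)
  expect_identical(unname(gv0$data[1]), unname(mm$means[["BACKGROUND"]]))
  expect_true(all(gv0$data == mm$means[lv$data + 1L]))
  gv1 <- render_grayscale(lv, mm, psf_sigma = 0.5, noise_sd = 5, seed = 2)
  gv2 <- render_grayscale(lv, mm, psf_sigma = 0.5, noise_sd = 5, seed = 2)
  gv3 <- render_grayscale(lv, mm, psf_sigma = 0.5, noise_sd = 5, seed = 3)
  expect_identical(gv1$data, gv2$data)
  expect_false(identical(gv1$data, gv3$data))
  expect_identical(dim(gv1$data), dim(lv$data))
  # interior Mg voxels keep the class mean within sampling error
  fx <- straight_strut(spacing = 0.02)
  gvn <- render_grayscale(fx$volume, mm, psf_sigma = 0, noise_sd = 8,
                          seed = 4)
  interior <- apply_degradation(fx$volume, fx$graph,
                                degradation_state(erosion_depth = 0.02,
                                                  seed = 1))$data == 3L
  n <- sum(interior)
  expect_lt(abs(mean(gvn$data[interior]) - mm$means[["MG_ALLOY"]]),
            2 * 8 / sqrt(n))
})

test_that("material model enforces the attenuation ordering", {
  expect_error(material_model(means = c(BACKGROUND = 20, TISSUE = 60,
                                        PRODUCT_LUCENT = 170, MG_ALLOY = 160,
                                        PRODUCT_DENSE = 230)),
               "strictly increasing")
  expect_error(degradation_state(substitution_fraction_dense = 0.7,
                                 substitution_fraction_lucent = 0.5),
               "sum to <= 1")
})
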