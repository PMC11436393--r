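test_that("segment_scaffold masks labels exactly and classifies grayscale", {
  g <- small_graph()
  lv <- voxelize(g, 0.02)
  m <- segment_scaffold(lv)
  expect_identical(m$data, array(lv$data == 3L | lv$data == 4L,
                                 dim = dim(lv$data)))
  # rendered with no blur/noise: voxel-level agreement >= 99%
  mm <- material_model()
  gv <- render_grayscale(lv, mm, psf_sigma = 0, noise_sd = 0)
  fit <- fit_peaks(compute_histogram(gv, 128), model = mm)
  mg <- segment_scaffold(gv, fit)
  expect_gte(mean(mg$data == m$data), 0.99)
  expect_error(segment_scaffold(gv), "histogram_fit")
  # all-tissue volume -> empty mask with warning
  tl <- label_volume(array(1L, dim = c(10, 10, 5)), 0.02)
  expect_warning(me <- segment_scaffold(tl), "empty")
  expect_false(any(me$data))
})

test_that("discontinuity ratio is exact for programmed cut lists", {
  g <- small_graph()        # 2 rings: 26 segments
  lv <- voxelize(g, 0.02)
  nseg <- length(g$segments)
  pristine <- discontinuity_ratio(segment_scaffold(lv), g)
  expect_identical(pristine$discontinuity_ratio, 0)
  expect_identical(pristine$n_fragments, 1L)
  for (ids in list(c(1L, 5L, 9L), 1:nseg)) {
    lvc <- apply_degradation(lv, g, degradation_state(cut_segment_ids = ids))
    m <- if (length(ids) == nseg) {
      suppressWarnings(segment_scaffold(lvc))
    } else segment_scaffold(lvc)
    ir <- suppressWarnings(discontinuity_ratio(m, g))
    expect_equal(ir$discontinuity_ratio, 100 * length(ids) / nseg)
  }
  # 3 cuts out of 138 on the full device: 2.17%
  g10 <- build_design(scaffold_design(n_rings = 10))
  expect_equal(100 * 3 / length(g10$segments), 2.17, tolerance = 1e-2)
})

test_that("discontinuity is monotone under added cuts and counts fragments", {
  g <- small_graph()
  lv <- voxelize(g, 0.02)
  prev <- -1
  for (ids in list(integer(0), 2L, c(2L, 7L), c(2L, 7L, 11L))) {
    lvc <- apply_degradation(lv, g, degradation_state(cut_segment_ids = ids))
    ir <- discontinuity_ratio(segment_scaffold(lvc), g)
    expect_gte(ir$discontinuity_ratio, prev)
    prev <- ir$discontinuity_ratio
  }
  # cutting both links separates the two rings into >= 2 fragments
  link_ids <- vapply(Filter(function(s) s$type == "link", g$segments),
                     `[[`, integer(1), "id")
  expect_length(link_ids, 2L)
  lvc <- apply_degradation(lv, g, degradation_state(cut_segment_ids = link_ids))
  ir <- discontinuity_ratio(segment_scaffold(lvc), g)
  expect_gte(ir$n_fragments, 2L)
})

test_that("inner area of an ideal tube matches pi r^2", {
  m <- tube_mask(inner_r = 1.4, spacing = 0.02)
  prof <- inner_area_profile(m, interval = 3.0)
  measurable <- prof$profile$area_mm2[!is.na(prof$profile$area_mm2)]
  expect_gt(length(measurable), 0)
  expect_lt(max(abs(measurable / (pi * 1.4^2) - 1)), 0.05)
})

test_that("slices with two struts are unmeasurable; empty masks propagate", {
  # two small blobs only
  arr <- array(FALSE, dim = c(100, 100, 2))
  arr[20:24, 50:54, ] <- TRUE
  arr[80:84, 50:54, ] <- TRUE
  m <- structure(list(data = arr, spacing = 0.02, origin = c(0, 0, 0)),
                 class = "scaffold_mask")
  prof <- inner_area_profile(m, interval = 3.0)
  expect_true(all(is.na(prof$profile$area_mm2)))
  empty <- structure(list(data = array(FALSE, dim = c(5, 5, 5)),
                          spacing = 0.02, origin = c(0, 0, 0)),
                     class = "scaffold_mask")
  expect_warning(p0 <- inner_area_profile(empty), "empty")
  expect_identical(nrow(p0$profile), 0L)
  ir <- suppressWarnings(discontinuity_ratio(empty, small_graph()))
  expect_identical(ir$discontinuity_ratio, 100)
})

test_that("uniformly dilated phantoms have larger inner areas", {
  base <- build_design(scaffold_design(n_rings = 1))
  dil <- build_design(scaffold_design(nominal_diameter = 3.3, n_rings = 1))
  a0 <- inner_area_profile(segment_scaffold(voxelize(base, 0.02)),
                           interval = 1.0)
  a1 <- inner_area_profile(segment_scaffold(voxelize(dil, 0.02)),
                           interval = 1.0)
  m0 <- a0$profile$area_mm2
  m1 <- a1$profile$area_mm2
  n <- min(length(m0), length(m1))
  ok <- !is.na(m0[1:n]) & !is.na(m1[1:n])
  expect_gt(sum(ok), 0)
  expect_true(all(m1[1:n][ok] > m0[1:n][ok]))
})

test_that("integrity exports write CSV and JSON", {
  g <- build_design(scaffold_design(n_rings = 1))
  lv <- voxelize(g, 0.02)
  ir <- discontinuity_ratio(segment_scaffold(lv), g)
  td <- withr::local_tempdir()
  paths <- export_integrity(ir, csv = file.path(td, "seg.csv"),
                            json = file.path(td, "seg.json"))
  expect_equal(nrow(read.csv(paths$csv)), length(g$segments))
  doc <- jsonlite::read_json(paths$json)
  expect_equal(doc$discontinuity_ratio, 0)
})
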