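test_that("segment counts follow the crown/link formula", {
  cases <- list(list(n_rings = 10, crowns = 6, links = 2, expect = 138L),
                list(n_rings = 1, crowns = 6, links = 2, expect = 12L),
                list(n_rings = 3, crowns = 4, links = 3, expect = 30L))
  for (cs in cases) {
    d <- scaffold_design(n_rings = cs$n_rings, crowns_per_ring = cs$crowns,
                         links_between_rings = cs$links)
    expect_identical(segment_count(d), cs$expect)
    g <- build_design(d)
    expect_length(g$segments, cs$expect)
  }
})

test_that("invalid parameters raise errors naming the field", {
  expect_error(scaffold_design(nominal_diameter = -1), "nominal_diameter")
  expect_error(scaffold_design(crowns_per_ring = 2), "crowns_per_ring")
  expect_error(scaffold_design(links_between_rings = 0), "links_between_rings")
  expect_error(scaffold_design(strut_width = 1), "strut_width")
  expect_error(scaffold_design(strut_thickness = 0.9), "strut_thickness")
  expect_error(scaffold_design(ring_pitch = 0.5, crown_amplitude = 0.4),
               "ring_pitch")
})

test_that("graph is connected and centerlines stay on the cylinder for random designs", {
  set.seed(101)
  for (i in 1:20) {
    d <- scaffold_design(
      nominal_diameter = runif(1, 2.5, 3.5),
      n_rings = sample(1:6, 1),
      crowns_per_ring = sample(3:8, 1),
      links_between_rings = sample(1:3, 1),
      ring_pitch = runif(1, 1.3, 2),
      crown_amplitude = runif(1, 0.3, 0.6))
    g <- build_design(d)
    expect_length(g$segments, segment_count(d))
    expect_true(igraph::is_connected(design_igraph(g)))
    r_outer <- d$nominal_diameter / 2
    r_inner <- r_outer - d$strut_thickness
    for (s in g$segments) {
      r <- sqrt(s$polyline[, 1]^2 + s$polyline[, 2]^2)
      expect_true(all(r <= r_outer + 1e-9 & r >= r_inner - 1e-9))
    }
  }
})

test_that("polyline lengths match numeric arc-length integration", {
  d <- scaffold_design()
  g <- build_design(d, points_per_arc = 40L)
  R <- (d$nominal_diameter - d$strut_thickness) / 2
  A <- d$crown_amplitude
  cc <- d$crowns_per_ring
  # independent oracle: arc length of (R cos t, R sin t, A sin(c t + phi))
  arc <- integrate(function(th) sqrt(R^2 + A^2 * cc^2 * cos(cc * th)^2),
                   0, pi / cc, rel.tol = 1e-10)$value
  limb <- g$segments[[1]]
  expect_equal(limb$length, arc, tolerance = 1e-3)
  expect_true(all(vapply(g$segments, `[[`, numeric(1), "length") >
                    d$crown_amplitude))
  # total length equals per-segment sum by construction; check the analytic
  # volume uses it
  expect_equal(design_volume(g),
               total_centerline_length(g) * d$strut_width * d$strut_thickness)
})

test_that("design exports round-trip through CSV and JSON", {
  g <- build_design(scaffold_design(n_rings = 2))
  td <- withr::local_tempdir()
  paths <- export_design(g, nodes_csv = file.path(td, "nodes.csv"),
                         segments_csv = file.path(td, "segments.csv"),
                         json = file.path(td, "design.json"))
  nodes <- read.csv(paths$nodes_csv)
  expect_equal(nrow(nodes), nrow(g$nodes))
  segs <- read.csv(paths$segments_csv)
  expect_equal(nrow(segs), length(g$segments))
  doc <- jsonlite::read_json(paths$json)
  expect_equal(length(doc$segments), length(g$segments))
  expect_equal(doc$design$crowns_per_ring, 6)
})
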