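# Fixtures are built in code; nothing is stored on disk.

# A free-standing straight strut along z (centerline at x = 0, y = 1), as a
# one-segment design graph plus its label volume. The grid is aligned so
# that strut surfaces fall midway between voxel centers (exact sampling):
# offset by half a voxel when the strut spans an even number of voxels.
straight_strut <- function(w = 0.1, h = w, L = 2, spacing = 0.02) {
  poly <- rbind(c(0, 1, 0), c(0, 1, L))
  design <- scaffold_design(nominal_diameter = 3, n_rings = 1,
                            strut_width = w, strut_thickness = h)
  graph <- structure(
    list(design = design,
         nodes = data.frame(id = 1:2, x = 0, y = 1, z = c(0, L)),
         segments = list(list(id = 1L, node_a = 1L, node_b = 2L,
                              type = "link", polyline = poly, length = L))),
    class = "design_graph")
  off_x <- if (round(w / spacing) %% 2 == 0) spacing / 2 else 0
  off_y <- if (round(h / spacing) %% 2 == 0) spacing / 2 else 0
  origin <- c(-0.3 + off_x, 0.7 + off_y, -0.2)
  dims <- c(ceiling(0.6 / spacing), ceiling(0.6 / spacing),
            ceiling((L + 0.4) / spacing))
  mg <- mgscaffold:::cpp_voxelize(as.integer(dims), spacing, origin,
                                  list(poly), h / 2, w / 2)
  arr <- array(MATERIAL_CLASSES[["TISSUE"]], dim = dims)
  arr[mg == 1L] <- MATERIAL_CLASSES[["MG_ALLOY"]]
  list(graph = graph, volume = label_volume(arr, spacing, origin))
}

# thin-walled tube mask (an intact vessel-like wall), z axis
tube_mask <- function(inner_r = 1.4, wall = 0.1, spacing = 0.02,
                      n_slices = 5L) {
  half <- inner_r + wall + 0.1
  n <- ceiling(2 * half / spacing) + 1L
  xc <- -half + spacing * (seq_len(n) - 1L)
  r2 <- outer(xc^2, xc^2, "+")
  disc <- r2 >= inner_r^2 & r2 <= (inner_r + wall)^2
  arr <- array(rep(disc, n_slices), dim = c(n, n, n_slices))
  structure(list(data = arr, spacing = spacing,
                 origin = c(-half, -half, 0)),
            class = "scaffold_mask")
}

small_graph <- function(n_rings = 2) build_design(scaffold_design(n_rings = n_rings))

# sample grayvalues from a programmed Gaussian mixture (oracle generator
# for peak-fitting recovery)
sample_mixture <- function(n, weights, means, sds, seed) {
  with_seed <- mgscaffold:::with_seed
  with_seed(seed, {
    comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    stats::rnorm(n, means[comp], sds[comp])
  })
}
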