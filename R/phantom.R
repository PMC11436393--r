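#' Grayscale material model
#'
#' Mean grayvalue (arbitrary units) and spread per material class. Means
#' must be strictly increasing in the attenuation order BACKGROUND < TISSUE
#' < PRODUCT_LUCENT < MG_ALLOY < PRODUCT_DENSE: the Ca/P-salt product is
#' brighter (less radiolucent) than the alloy, the MgO-type product darker.
#' The spreads are not injected during rendering (global `noise_sd` controls
#' image noise); they describe the expected per-class histogram width and
#' seed the peak-fitting initialization.
#'
#' @param means Named numeric vector of class mean grayvalues.
#' @param sds Named numeric vector of class grayvalue spreads.
#' @return An object of class `material_model`.
#' @export
material_model <- function(means = c(BACKGROUND = 20, TISSUE = 60,
                                     PRODUCT_LUCENT = 105, MG_ALLOY = 160,
                                     PRODUCT_DENSE = 230),
                           sds = c(BACKGROUND = 6, TISSUE = 6,
                                   PRODUCT_LUCENT = 8, MG_ALLOY = 8,
                                   PRODUCT_DENSE = 10)) {
  cls <- names(MATERIAL_CLASSES)
  if (!identical(names(means), cls)) {
    abort_field("means", "must be named with the five material classes")
  }
  if (!identical(names(sds), cls)) {
    abort_field("sds", "must be named with the five material classes")
  }
  if (any(diff(means) <= 0)) {
    abort_field("means",
                "must be strictly increasing BACKGROUND < TISSUE < PRODUCT_LUCENT < MG_ALLOY < PRODUCT_DENSE")
  }
  if (any(sds <= 0)) abort_field("sds", "must be positive")
  structure(list(means = means, sds = sds), class = "material_model")
}

#' Degradation state of a phantom
#'
#' Describes how far degradation has progressed when the phantom is
#' rendered: isotropic surface recession depth (per exposed face), the
#' fractions of eroded alloy replaced by radiodense (Ca/P-like) and
#' radiolucent (MgO-like) products (the remainder is resorbed to tissue),
#' the set of fractured segments, and the RNG seed for the per-voxel
#' substitution draw.
#'
#' @param time Implantation time (months), metadata only.
#' @param erosion_depth Recession depth per face (mm), typically `k * time`.
#' @param substitution_fraction_dense,substitution_fraction_lucent Fractions
#'   in `[0, 1]`, summing to at most 1.
#' @param cut_segment_ids Integer ids of segments removed by fracture.
#' @param precipitate_size Edge length (mm) of the blocks over which the
#'   substitution draw is constant: degradation products form contiguous
#'   precipitates of roughly this size rather than voxel-wise speckle
#'   (which a realistic point-spread function would average into a
#'   featureless alloy-like grayvalue). `0` gives independent per-voxel
#'   draws.
#' @param seed RNG seed for the substitution draw.
#' @return An object of class `degradation_state`.
#' @export
degradation_state <- function(time = 0, erosion_depth = 0,
                              substitution_fraction_dense = 0.5,
                              substitution_fraction_lucent = 0.3,
                              cut_segment_ids = integer(0),
                              precipitate_size = 0.06,
                              seed = 1L) {
  check_scalar_num(time, "time", 0)
  check_scalar_num(erosion_depth, "erosion_depth", 0)
  check_scalar_num(substitution_fraction_dense,
                   "substitution_fraction_dense", 0, 1)
  check_scalar_num(substitution_fraction_lucent,
                   "substitution_fraction_lucent", 0, 1)
  if (substitution_fraction_dense + substitution_fraction_lucent > 1 + 1e-12) {
    abort_field("substitution_fraction_dense",
                "substitution fractions must sum to <= 1")
  }
  check_scalar_num(precipitate_size, "precipitate_size", 0)
  structure(list(time = time, erosion_depth = erosion_depth,
                 substitution_fraction_dense = substitution_fraction_dense,
                 substitution_fraction_lucent = substitution_fraction_lucent,
                 cut_segment_ids = as.integer(cut_segment_ids),
                 precipitate_size = precipitate_size,
                 seed = as.integer(seed)),
            class = "degradation_state")
}

#' Voxelize a design graph into a label volume
#'
#' Rasterizes the rectangular strut cross-section (thickness radial, width
#' tangential) swept along every segment centerline as MG_ALLOY, embeds the
#' device in a coaxial tissue annulus (vessel wall plus neointimal
#' coverage), and fills the rest with BACKGROUND. The grid is voxel-centered
#' with the device axis along z through x = y = 0.
#'
#' @param graph A `design_graph`.
#' @param spacing Isotropic voxel size (mm); must be at most
#'   `strut_thickness / 4` so a strut spans >= 4 voxels.
#' @param tissue_inner,tissue_outer Radial extent of the tissue annulus,
#'   relative to the strut centerline radius (mm).
#' @param pad Spatial padding beyond the annulus / device ends (mm).
#' @return A `label_volume`.
#' @export
voxelize <- function(graph, spacing = 0.02, tissue_inner = 0.3,
                     tissue_outer = 0.45, pad = 0.15) {
  stopifnot(inherits(graph, "design_graph"))
  d <- graph$design
  if (spacing > d$strut_thickness / 4 + 1e-12) {
    stop(sprintf(
      "spacing %g mm too coarse: need <= strut_thickness / 4 = %g mm (>= 4 voxels across a strut)",
      spacing, d$strut_thickness / 4), call. = FALSE)
  }
  R <- (d$nominal_diameter - d$strut_thickness) / 2
  r_out <- R + tissue_outer
  polys <- lapply(graph$segments, `[[`, "polyline")
  if (length(polys)) {
    zr <- range(unlist(lapply(polys, function(p) range(p[, 3]))))
  } else {
    zr <- c(0, 0)
  }
  half_xy <- r_out + pad
  z0 <- zr[1] - d$strut_thickness / 2 - pad
  z1 <- zr[2] + d$strut_thickness / 2 + pad
  nx <- ceiling(2 * half_xy / spacing) + 1L
  nz <- ceiling((z1 - z0) / spacing) + 1L
  origin <- c(-half_xy, -half_xy, z0)
  dims <- c(nx, nx, nz)

  mg <- cpp_voxelize(as.integer(dims), spacing, origin, polys,
                     d$strut_thickness / 2, d$strut_width / 2)
  # tissue annulus
  xc <- origin[1] + spacing * (seq_len(nx) - 1L)
  r2 <- outer(xc^2, xc^2, "+")
  annulus <- r2 >= (R - tissue_inner)^2 & r2 <= r_out^2
  lab <- array(MATERIAL_CLASSES[["BACKGROUND"]], dim = dims)
  lab[rep(annulus, times = nz)] <- MATERIAL_CLASSES[["TISSUE"]]
  lab[mg == 1L] <- MATERIAL_CLASSES[["MG_ALLOY"]]
  label_volume(lab, spacing, origin)
}

# voxel membership masks of individual segments (same grid as `vol`)
segment_voxels <- function(vol, graph, ids) {
  d <- graph$design
  polys <- lapply(graph$segments[ids], `[[`, "polyline")
  cpp_voxelize(as.integer(dim(vol$data)), vol$spacing, vol$origin, polys,
               d$strut_thickness / 2, d$strut_width / 2) == 1L
}

#' Apply a degradation state to a label volume
#'
#' Isotropic surface erosion: MG_ALLOY voxels within `erosion_depth` of the
#' alloy surface are reassigned — a seeded per-voxel draw sends them to
#' PRODUCT_DENSE / PRODUCT_LUCENT / TISSUE with the state's substitution
#' fractions. With `method = "analytic"` (default) the depth below the
#' surface is computed exactly from the swept strut geometry, so eroding by
#' `d` reproduces the continuum shrinkage of the cross-section by `d` per
#' face; `method = "edt"` uses the voxel Euclidean distance transform from
#' non-alloy voxels instead (surface taken half a voxel beyond the outermost
#' alloy centers), which over-erodes tilted struts by up to ~0.4 voxel.
#' Fractured segments (`cut_segment_ids`) then lose all their voxels except
#' junction material shared with an uncut segment, so cutting one segment
#' never disconnects its neighbours.
#'
#' @param vol A `label_volume` on the same grid the graph was voxelized to.
#' @param graph The `design_graph` the volume was built from.
#' @param state A `degradation_state`.
#' @param method Depth-below-surface estimator: `"analytic"` (swept
#'   geometry) or `"edt"` (voxel distance transform).
#' @return A new `label_volume`.
#' @export
apply_degradation <- function(vol, graph, state,
                              method = c("analytic", "edt")) {
  stopifnot(inherits(vol, "label_volume"), inherits(graph, "design_graph"),
            inherits(state, "degradation_state"))
  method <- match.arg(method)
  ids <- vapply(graph$segments, `[[`, integer(1), "id")
  if (length(state$cut_segment_ids) &&
      !all(state$cut_segment_ids %in% ids)) {
    bad <- setdiff(state$cut_segment_ids, ids)
    stop(sprintf("unknown segment id(s) in cut list: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  lab <- vol$data
  mg <- lab == MATERIAL_CLASSES[["MG_ALLOY"]]

  if (state$erosion_depth > 0 && any(mg)) {
    if (method == "analytic") {
      d <- graph$design
      depth_mm <- cpp_voxelize_depth(
        as.integer(dim(lab)), vol$spacing, vol$origin,
        lapply(graph$segments, `[[`, "polyline"),
        d$strut_thickness / 2, d$strut_width / 2)
    } else {
      sqd <- cpp_sqdist_to_zero(as.integer(mg), as.integer(dim(lab)))
      depth_mm <- sqrt(sqd) * vol$spacing - vol$spacing / 2
    }
    eroded <- which(mg & depth_mm <= state$erosion_depth + 1e-12)
    if (length(eroded)) {
      bs <- max(1L, round(state$precipitate_size / vol$spacing))
      if (bs > 1L) {
        # one draw per precipitate block, constant within the block
        ijk <- idx_to_ijk(eroded, dim(lab))
        blk <- (ijk - 1L) %/% bs
        key <- blk[, 1] + 100000 * (blk[, 2] + 100000 * blk[, 3])
        uk <- unique(key)
        u <- with_seed(state$seed,
                       stats::runif(length(uk)))[match(key, uk)]
      } else {
        u <- with_seed(state$seed, stats::runif(length(eroded)))
      }
      fd <- state$substitution_fraction_dense
      fl <- state$substitution_fraction_lucent
      cls <- ifelse(u < fd, MATERIAL_CLASSES[["PRODUCT_DENSE"]],
                    ifelse(u < fd + fl, MATERIAL_CLASSES[["PRODUCT_LUCENT"]],
                           MATERIAL_CLASSES[["TISSUE"]]))
      lab[eroded] <- as.integer(cls)
    }
  }

  if (length(state$cut_segment_ids)) {
    cut <- segment_voxels(vol, graph, match(state$cut_segment_ids, ids))
    keep_ids <- setdiff(ids, state$cut_segment_ids)
    if (length(keep_ids)) {
      kept <- segment_voxels(vol, graph, match(keep_ids, ids))
      cut <- cut & !kept
    }
    scaffold_cls <- c(MATERIAL_CLASSES[["PRODUCT_LUCENT"]],
                      MATERIAL_CLASSES[["MG_ALLOY"]],
                      MATERIAL_CLASSES[["PRODUCT_DENSE"]])
    sel <- cut & (lab %in% scaffold_cls)
    lab[sel] <- MATERIAL_CLASSES[["TISSUE"]]
  }
  label_volume(lab, vol$spacing, vol$origin)
}

#' Render a label volume to a grayscale micro-CT-like volume
#'
#' Replaces each voxel by its class mean grayvalue, convolves with an
#' isotropic Gaussian point-spread function (partial-volume blur), and adds
#' seeded zero-mean Gaussian noise.
#'
#' @param vol A `label_volume`.
#' @param model A `material_model`.
#' @param psf_sigma PSF standard deviation in voxels (>= 0).
#' @param noise_sd Additive noise standard deviation (grayvalue units, >= 0).
#' @param seed RNG seed for the noise draw.
#' @return A `voxel_volume`.
#' @export
render_grayscale <- function(vol, model = material_model(), psf_sigma = 1,
                             noise_sd = 0, seed = 1L) {
  stopifnot(inherits(vol, "label_volume"), inherits(model, "material_model"))
  check_scalar_num(psf_sigma, "psf_sigma", 0)
  check_scalar_num(noise_sd, "noise_sd", 0)
  img <- model$means[vol$data + 1L]
  dim(img) <- dim(vol$data)
  if (psf_sigma > 0) {
    img <- array(cpp_gaussian_blur(as.numeric(img), as.integer(dim(img)),
                                   psf_sigma), dim = dim(img))
  }
  if (noise_sd > 0) {
    img <- img + with_seed(seed, stats::rnorm(length(img), 0, noise_sd))
  }
  voxel_volume(img, vol$spacing, vol$origin)
}
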