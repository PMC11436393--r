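#' Segment visible strut material from a volume
#'
#' Produces the binary scaffold mask used by the integrity measurements:
#' voxels that are magnesium alloy or radiodense degradation product (the
#' strut material visible in micro-CT). Label volumes are masked by class;
#' grayscale volumes are classified voxel-wise by maximum posterior under a
#' fitted Gaussian mixture (each component carries a material class).
#'
#' @param vol A `label_volume` or `voxel_volume`.
#' @param fit A `histogram_fit`; required for grayscale input.
#' @return An object of class `scaffold_mask`: logical array plus `spacing`
#'   and `origin`. An empty mask triggers a warning; downstream operations
#'   then report 100% discontinuity / unmeasurable areas.
#' @export
segment_scaffold <- function(vol, fit = NULL) {
  if (inherits(vol, "label_volume")) {
    m <- vol$data == MATERIAL_CLASSES[["MG_ALLOY"]] |
      vol$data == MATERIAL_CLASSES[["PRODUCT_DENSE"]]
  } else if (inherits(vol, "voxel_volume")) {
    if (is.null(fit)) {
      stop("grayscale input requires a histogram_fit for classification",
           call. = FALSE)
    }
    v <- as.vector(vol$data)
    best_d <- rep(-Inf, length(v))
    best_j <- integer(length(v))
    for (j in seq_len(fit$k)) {
      dj <- fit$components$weight[j] *
        stats::dnorm(v, fit$components$mean[j], fit$components$sd[j])
      sel <- dj > best_d
      best_d[sel] <- dj[sel]
      best_j[sel] <- j
    }
    cls <- fit$components$class[best_j]
    m <- array(cls == "MG_ALLOY" | cls == "PRODUCT_DENSE",
               dim = dim(vol$data))
  } else {
    stop("vol must be a label_volume or voxel_volume", call. = FALSE)
  }
  if (!any(m)) warning("empty scaffold mask")
  structure(list(data = m, spacing = vol$spacing, origin = vol$origin),
            class = "scaffold_mask")
}

# voxel indices -> integer grid coordinates (1-based)
idx_to_ijk <- function(idx, dims) {
  i <- (idx - 1L) %% dims[1]
  j <- ((idx - 1L) %/% dims[1]) %% dims[2]
  k <- (idx - 1L) %/% (dims[1] * dims[2])
  cbind(i, j, k) + 1L
}

# connectivity of one segment: is there a 26-connected path of mask voxels
# inside the capture tube joining the two endpoint node neighbourhoods?
segment_continuous <- function(mask, polyline, node_a, node_b, radius) {
  dims <- dim(mask$data)
  idx <- cpp_near_polyline(as.integer(dims), mask$spacing, mask$origin,
                           polyline, radius)
  idx <- idx[mask$data[idx]]
  if (!length(idx)) return(FALSE)
  ijk <- idx_to_ijk(idx, dims)
  xyz <- sweep((ijk - 1L) * mask$spacing, 2, mask$origin, "+")
  near <- function(node) {
    rowSums(sweep(xyz, 2, node, "-")^2) <= radius^2
  }
  at_a <- near(node_a)
  at_b <- near(node_b)
  if (!any(at_a) || !any(at_b)) return(FALSE)
  # label the tube voxels inside their bounding box only
  lo <- apply(ijk, 2, min)
  hi <- apply(ijk, 2, max)
  bdims <- hi - lo + 1L
  sub <- array(FALSE, dim = bdims)
  rel <- sweep(ijk, 2, lo, "-") + 1L
  sub[rel] <- TRUE
  lab <- array(cpp_label_components(as.integer(sub), as.integer(bdims), 26L),
               dim = bdims)
  la <- unique(lab[rel[at_a, , drop = FALSE]])
  lb <- unique(lab[rel[at_b, , drop = FALSE]])
  length(intersect(la, lb)) > 0
}

#' Strut discontinuity ratio
#'
#' A designed segment is CONTINUOUS iff its two endpoint nodes are joined by
#' a 26-connected path of mask voxels lying within a capture radius of the
#' segment centerline; the discontinuity ratio is the percentage of
#' discontinuous segments. The fragment count is the number of 3D connected
#' components of the whole mask.
#'
#' @param mask A `scaffold_mask` in the same physical frame as the graph
#'   (phantoms: identity registration; anything else must be pre-registered,
#'   `registration = "rigid"` input is not implemented for real scans).
#' @param graph The `design_graph`.
#' @param capture_radius Capture tube radius (mm); default 1.5 x strut
#'   width, tolerating partial-volume bloom without bridging the lumen.
#' @param registration `"none"` (identity) only.
#' @return An object of class `integrity_result`: `per_segment` (data.frame
#'   id, type, continuity), `discontinuity_ratio` (percent), `n_fragments`,
#'   `n_segments`.
#' @export
discontinuity_ratio <- function(mask, graph, capture_radius = NULL,
                                registration = c("none", "rigid")) {
  stopifnot(inherits(mask, "scaffold_mask"), inherits(graph, "design_graph"))
  registration <- match.arg(registration)
  if (registration != "none") {
    stop("rigid registration of real scans is not implemented; ",
         "supply pre-registered input", call. = FALSE)
  }
  if (is.null(capture_radius)) {
    capture_radius <- 1.5 * graph$design$strut_width
  }
  check_scalar_num(capture_radius, "capture_radius", 0, strict_lower = TRUE)
  nodes <- as.matrix(graph$nodes[, c("x", "y", "z")])
  empty <- !any(mask$data)
  cont <- vapply(graph$segments, function(s) {
    if (empty) return(FALSE)
    segment_continuous(mask, s$polyline, nodes[s$node_a, ],
                       nodes[s$node_b, ], capture_radius)
  }, logical(1))
  nfrag <- if (empty) 0L else {
    attr(cpp_label_components(as.integer(mask$data),
                              as.integer(dim(mask$data)), 26L),
         "n_components")
  }
  per <- data.frame(
    id = vapply(graph$segments, `[[`, integer(1), "id"),
    type = vapply(graph$segments, `[[`, character(1), "type"),
    continuity = ifelse(cont, "CONTINUOUS", "DISCONTINUOUS"),
    stringsAsFactors = FALSE)
  structure(list(per_segment = per,
                 discontinuity_ratio = 100 * sum(!cont) / length(cont),
                 n_fragments = nfrag,
                 n_segments = length(cont)),
            class = "integrity_result")
}

#' @export
print.integrity_result <- function(x, ...) {
  cat(sprintf(
    "integrity_result: %.2f%% discontinuity (%d/%d segments), %d fragment(s)\n",
    x$discontinuity_ratio,
    sum(x$per_segment$continuity == "DISCONTINUOUS"),
    x$n_segments, x$n_fragments))
  invisible(x)
}

# inner polygon area of one 2D slice; returns NA_real_ when unmeasurable
slice_inner_area <- function(slice, spacing, min_components = 3L,
                             coverage_deg = 300, n_bins = 36L) {
  if (!any(slice)) return(NA_real_)
  dims <- c(dim(slice), 1L)
  labv <- cpp_label_components(as.integer(slice), as.integer(dims), 26L)
  ncomp <- attr(labv, "n_components")
  lab <- array(labv, dim = dim(slice))
  idx <- which(slice)
  ij <- cbind((idx - 1L) %% dims[1], (idx - 1L) %/% dims[1]) + 1L
  xy <- ij * spacing
  ctr <- colMeans(xy)
  rel <- sweep(xy, 2, ctr, "-")
  r <- sqrt(rowSums(rel^2))
  ang <- atan2(rel[, 2], rel[, 1])
  pts <- NULL
  if (ncomp >= min_components) {
    # innermost point of each connected strut cross-section
    comp <- lab[idx]
    inner <- vapply(seq_len(ncomp), function(cc) {
      sel <- which(comp == cc)
      sel[which.min(r[sel])]
    }, integer(1))
    pts <- cbind(rel[inner, 1], rel[inner, 2])
  } else {
    # an encircling wall (e.g. an intact tube): use per-angular-bin
    # innermost radii when the mask covers >= coverage_deg of the circle
    occ5 <- unique(floor((ang + pi) / (2 * pi) * 72))
    if (length(occ5) * 5 < coverage_deg) return(NA_real_)
    bin <- floor((ang + pi) / (2 * pi) * n_bins)
    inner <- vapply(unique(bin), function(b) {
      sel <- which(bin == b)
      sel[which.min(r[sel])]
    }, integer(1))
    if (length(inner) < 3) return(NA_real_)
    pts <- cbind(rel[inner, 1], rel[inner, 2])
  }
  o <- order(atan2(pts[, 2], pts[, 1]))
  p <- pts[o, , drop = FALSE]
  nx <- nrow(p)
  nxt <- c(2:nx, 1)
  abs(sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2])) / 2
}

#' Scaffold inner-area profile
#'
#' Measures the scaffold inner area on 2D cross-sections at fixed axial
#' intervals (default 3 mm), starting at the first slice containing mask
#' voxels. On each slice the area is that of the polygon through the
#' innermost point (minimum radius from the slice centroid) of each strut
#' cross-section, vertices sorted by angle. Slices with fewer than 3 strut
#' components are unmeasurable (`NA`) unless the mask forms an encircling
#' wall, in which case per-angular-bin innermost radii are used.
#'
#' @param mask A `scaffold_mask` with z along the device axis.
#' @param interval Axial sampling interval (mm).
#' @return An object of class `inner_area_profile`: data.frame
#'   (`position_mm` from the first occupied slice, `area_mm2` with `NA` =
#'   UNMEASURABLE) plus `mean_area`.
#' @export
inner_area_profile <- function(mask, interval = 3.0) {
  stopifnot(inherits(mask, "scaffold_mask"))
  check_scalar_num(interval, "interval", 0, strict_lower = TRUE)
  dims <- dim(mask$data)
  occ <- which(apply(mask$data, 3, any))
  if (!length(occ)) {
    warning("empty scaffold mask: no measurable slices")
    prof <- data.frame(position_mm = numeric(0), area_mm2 = numeric(0))
    return(structure(list(profile = prof, mean_area = NA_real_),
                     class = "inner_area_profile"))
  }
  step <- max(1L, floor(interval / mask$spacing))
  zsel <- seq(occ[1], dims[3], by = step)
  areas <- vapply(zsel, function(z) {
    slice_inner_area(mask$data[, , z], mask$spacing)
  }, numeric(1))
  prof <- data.frame(position_mm = (zsel - occ[1]) * mask$spacing,
                     area_mm2 = areas)
  structure(list(profile = prof,
                 mean_area = if (all(is.na(areas))) NA_real_
                             else mean(areas, na.rm = TRUE)),
            class = "inner_area_profile")
}

#' @export
print.inner_area_profile <- function(x, ...) {
  cat(sprintf("inner_area_profile: %d slices, mean area %.3f mm^2\n",
              nrow(x$profile), x$mean_area))
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' Export integrity results to CSV / JSON
#' @param result An `integrity_result` or `inner_area_profile`.
#' @param csv,json Output paths (`NULL` skips).
#' @return Invisibly, the paths written.
#' @export
export_integrity <- function(result, csv = NULL, json = NULL) {
  out <- list()
  tab <- if (inherits(result, "integrity_result")) result$per_segment
         else result$profile
  if (!is.null(csv)) {
    utils::write.csv(tab, csv, row.names = FALSE)
    out$csv <- csv
  }
  if (!is.null(json)) {
    jsonlite::write_json(unclass(result), json, auto_unbox = TRUE,
                         digits = NA, na = "null", dataframe = "rows")
    out$json <- json
  }
  invisible(out)
}
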