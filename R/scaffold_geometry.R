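#' Parametric scaffold design
#'
#' Describes a balloon-expandable coronary scaffold as a stack of sinusoidal
#' rings ("crowns") joined by axial links, the layout used by six-crown /
#' two-link bioresorbable magnesium devices. All lengths are in millimetres.
#'
#' @param nominal_diameter Expanded device diameter (mm).
#' @param n_rings Number of crown rings along the device axis.
#' @param crowns_per_ring Crowns (sinusoid peaks) per ring.
#' @param links_between_rings Axial links joining each adjacent ring pair.
#' @param strut_width Strut width, tangential to the vessel wall (mm).
#' @param strut_thickness Strut thickness, radial (mm).
#' @param ring_pitch Axial centre-to-centre distance of adjacent rings (mm).
#' @param crown_amplitude Half peak-to-valley axial amplitude of a ring (mm).
#'
#' @return An object of class `scaffold_design`.
#' @examples
#' d <- scaffold_design(nominal_diameter = 3, n_rings = 10)
#' segment_count(d)
#' @export
scaffold_design <- function(nominal_diameter = 3.0,
                            n_rings = 10L,
                            crowns_per_ring = 6L,
                            links_between_rings = 2L,
                            strut_width = 0.11,
                            strut_thickness = 0.11,
                            ring_pitch = 1.5,
                            crown_amplitude = 0.45) {
  check_scalar_num(nominal_diameter, "nominal_diameter", 0, strict_lower = TRUE)
  n_rings <- check_count(n_rings, "n_rings", min = 1L)
  crowns_per_ring <- check_count(crowns_per_ring, "crowns_per_ring", min = 3L)
  links_between_rings <- check_count(links_between_rings,
                                     "links_between_rings", min = 1L)
  check_scalar_num(strut_width, "strut_width", 0, strict_lower = TRUE)
  check_scalar_num(strut_thickness, "strut_thickness", 0, strict_lower = TRUE)
  check_scalar_num(ring_pitch, "ring_pitch", 0, strict_lower = TRUE)
  check_scalar_num(crown_amplitude, "crown_amplitude", 0, strict_lower = TRUE)
  if (strut_width >= nominal_diameter / 4) {
    abort_field("strut_width", "must be < nominal_diameter / 4")
  }
  if (strut_thickness >= nominal_diameter / 4) {
    abort_field("strut_thickness", "must be < nominal_diameter / 4")
  }
  if (links_between_rings > crowns_per_ring) {
    abort_field("links_between_rings", "cannot exceed crowns_per_ring")
  }
  if (n_rings > 1L && ring_pitch <= 2 * crown_amplitude) {
    abort_field("ring_pitch",
                "must exceed 2 * crown_amplitude so adjacent rings do not overlap")
  }
  structure(
    list(nominal_diameter = nominal_diameter,
         n_rings = n_rings,
         crowns_per_ring = crowns_per_ring,
         links_between_rings = links_between_rings,
         strut_width = strut_width,
         strut_thickness = strut_thickness,
         ring_pitch = ring_pitch,
         crown_amplitude = crown_amplitude),
    class = "scaffold_design")
}

#' @export
print.scaffold_design <- function(x, ...) {
  cat(sprintf(
    "scaffold_design: %g mm x %d rings (%d crowns, %d links), strut %g x %g mm\n",
    x$nominal_diameter, x$n_rings, x$crowns_per_ring, x$links_between_rings,
    x$strut_width, x$strut_thickness))
  invisible(x)
}

#' Number of strut segments in a design
#'
#' Each crown contributes two limb segments (apex-to-valley arcs) and each
#' adjacent ring pair contributes `links_between_rings` link segments:
#' `n_rings * 2 * crowns_per_ring + (n_rings - 1) * links_between_rings`.
#'
#' @param design A `scaffold_design`.
#' @return Integer segment count.
#' @export
segment_count <- function(design) {
  stopifnot(inherits(design, "scaffold_design"))
  design$n_rings * 2L * design$crowns_per_ring +
    (design$n_rings - 1L) * design$links_between_rings
}

# Angular node positions of ring i (1-based). Extremum m (0-based, 2c of
# them) sits at c*theta + phase = pi/2 + pi*m; even m are apexes (+A),
# odd m are valleys (-A). Alternate rings are phase-shifted by pi so an apex
# of ring i faces a valley of ring i+1 at the same angle.
ring_phase <- function(i) pi * ((i - 1L) %% 2L)

#' Build a scaffold design graph
#'
#' Decomposes the design into its strut-segment centerline graph: nodes are
#' crown apexes/valleys (which double as link junctions), segments are crown
#' limbs (apex-to-valley sinusoid arcs on the cylinder of radius
#' `(nominal_diameter - strut_thickness) / 2`) plus straight links between
#' facing apex/valley pairs of adjacent rings. The graph is the ground truth
#' for phantom voxelization and for discontinuity accounting.
#'
#' @param design A `scaffold_design` (or arguments forwarded to
#'   [scaffold_design()] when `design` is missing).
#' @param points_per_arc Polyline sampling density per crown limb.
#' @return An object of class `design_graph`: a list with `design`, `nodes`
#'   (data.frame: id, x, y, z in mm), and `segments` (list of lists with
#'   `id`, `node_a`, `node_b`, `type`, `polyline` (n x 3 matrix, mm),
#'   `length`).
#' @examples
#' g <- build_design(scaffold_design(n_rings = 2))
#' length(g$segments)
#' @export
build_design <- function(design = scaffold_design(), points_per_arc = 15L) {
  stopifnot(inherits(design, "scaffold_design"))
  points_per_arc <- check_count(points_per_arc, "points_per_arc", min = 3L)
  c_ <- design$crowns_per_ring
  A <- design$crown_amplitude
  R <- (design$nominal_diameter - design$strut_thickness) / 2
  pitch <- design$ring_pitch

  ring_z <- function(i, theta) {
    (i - 1L) * pitch + A * sin(c_ * theta + ring_phase(i))
  }

  nodes <- list()
  node_id <- function(ring, m) as.integer((ring - 1L) * 2L * c_ + m + 1L)
  for (i in seq_len(design$n_rings)) {
    for (m in 0:(2L * c_ - 1L)) {
      theta <- (pi / 2 + pi * m - ring_phase(i)) / c_
      nodes[[node_id(i, m)]] <- c(R * cos(theta), R * sin(theta),
                                  ring_z(i, theta))
    }
  }
  node_mat <- do.call(rbind, nodes)

  segments <- list()
  sid <- 0L
  for (i in seq_len(design$n_rings)) {
    for (m in 0:(2L * c_ - 1L)) {
      m2 <- (m + 1L) %% (2L * c_)
      th_a <- (pi / 2 + pi * m - ring_phase(i)) / c_
      th_b <- th_a + pi / c_   # consecutive extremum, unwrapped
      th <- seq(th_a, th_b, length.out = points_per_arc)
      poly <- cbind(R * cos(th), R * sin(th), ring_z(i, th))
      sid <- sid + 1L
      segments[[sid]] <- list(id = sid, node_a = node_id(i, m),
                              node_b = node_id(i, m2), type = "crown_limb",
                              polyline = poly)
    }
  }
  if (design$n_rings > 1L) {
    link_apex <- as.integer(floor(c_ * (0:(design$links_between_rings - 1L)) /
                                    design$links_between_rings))
    for (i in seq_len(design$n_rings - 1L)) {
      for (j in link_apex) {
        # apex node (even extremum 2j) of ring i faces valley (odd extremum
        # 2j+1) of ring i+1 at the same angle
        na <- node_id(i, 2L * j)
        nb <- node_id(i + 1L, 2L * j + 1L)
        poly <- rbind(node_mat[na, ], node_mat[nb, ])
        sid <- sid + 1L
        segments[[sid]] <- list(id = sid, node_a = na, node_b = nb,
                                type = "link", polyline = poly)
      }
    }
  }
  for (s in seq_along(segments)) {
    p <- segments[[s]]$polyline
    segments[[s]]$length <- sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                                              p[-nrow(p), , drop = FALSE])^2)))
  }

  graph <- structure(
    list(design = design,
         nodes = data.frame(id = seq_len(nrow(node_mat)),
                            x = node_mat[, 1], y = node_mat[, 2],
                            z = node_mat[, 3]),
         segments = segments),
    class = "design_graph")
  stopifnot(length(segments) == segment_count(design))
  graph
}

#' @export
print.design_graph <- function(x, ...) {
  cat(sprintf("design_graph: %d nodes, %d segments, total length %.2f mm\n",
              nrow(x$nodes), length(x$segments), total_centerline_length(x)))
  invisible(x)
}

#' Total centerline length of a design graph (mm)
#' @param graph A `design_graph`.
#' @export
total_centerline_length <- function(graph) {
  stopifnot(inherits(graph, "design_graph"))
  sum(vapply(graph$segments, `[[`, numeric(1), "length"))
}

#' Analytic as-manufactured scaffold volume (mm^3)
#'
#' Sum of segment centerline length times the rectangular strut
#' cross-section. Junction overlap is ignored (each junction is shared by
#' 2-3 segments over about one strut width), so this slightly overestimates
#' the swept solid; the voxelized volume is checked against it to 10%.
#'
#' @param graph A `design_graph`.
#' @export
design_volume <- function(graph) {
  stopifnot(inherits(graph, "design_graph"))
  d <- graph$design
  total_centerline_length(graph) * d$strut_width * d$strut_thickness
}

#' Strut-segment connectivity as an igraph object
#' @param graph A `design_graph`.
#' @return An `igraph` graph whose vertices are nodes and whose edges are
#'   segments (edge attribute `segment_id`).
#' @export
design_igraph <- function(graph) {
  stopifnot(inherits(graph, "design_graph"))
  edges <- t(vapply(graph$segments,
                    function(s) c(s$node_a, s$node_b), integer(2)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$segment_id <- vapply(graph$segments, `[[`, integer(1), "id")
  g
}

#' Export a design graph to CSV or JSON
#'
#' @param graph A `design_graph`.
#' @param nodes_csv,segments_csv,json Output paths; `NULL` skips that output.
#' @return Invisibly, the list of paths written.
#' @export
export_design <- function(graph, nodes_csv = NULL, segments_csv = NULL,
                          json = NULL) {
  stopifnot(inherits(graph, "design_graph"))
  written <- list()
  if (!is.null(nodes_csv)) {
    utils::write.csv(graph$nodes, nodes_csv, row.names = FALSE)
    written$nodes_csv <- nodes_csv
  }
  if (!is.null(segments_csv)) {
    seg <- do.call(rbind, lapply(graph$segments, function(s) {
      data.frame(id = s$id, node_a = s$node_a, node_b = s$node_b,
                 type = s$type, length_mm = s$length)
    }))
    utils::write.csv(seg, segments_csv, row.names = FALSE)
    written$segments_csv <- segments_csv
  }
  if (!is.null(json)) {
    doc <- list(
      design = unclass(graph$design),
      nodes = graph$nodes,
      segments = lapply(graph$segments, function(s) {
        list(id = s$id, node_a = s$node_a, node_b = s$node_b, type = s$type,
             length_mm = s$length,
             polyline = apply(s$polyline, 1, function(p) as.list(p),
                              simplify = FALSE))
      }))
    jsonlite::write_json(doc, json, auto_unbox = TRUE, digits = NA)
    written$json <- json
  }
  invisible(written)
}
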