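#' Intensity histogram of a grayscale volume
#'
#' @param volume A `voxel_volume` or numeric vector of grayvalues.
#' @param n_bins Number of equal-width bins (>= 16).
#' @param mask Optional logical array/vector selecting voxels (e.g. a
#'   cylindrical region of interest from [roi_cylinder()]).
#' @return An object of class `ct_histogram`: `breaks`, `mids`, `counts`,
#'   `n`, `bin_width`, `spacing` (mm, `NA` for bare vectors), `constant`
#'   flag (single occupied bin).
#' @export
compute_histogram <- function(volume, n_bins = 256L, mask = NULL) {
  n_bins <- check_count(n_bins, "n_bins", min = 16L)
  spacing <- NA_real_
  if (inherits(volume, "voxel_volume")) {
    spacing <- volume$spacing
    v <- as.vector(volume$data)
  } else {
    v <- as.numeric(volume)
  }
  if (!is.null(mask)) v <- v[as.logical(mask)]
  stopifnot(length(v) > 0, all(is.finite(v)))
  rng <- range(v)
  if (rng[1] == rng[2]) {
    # constant image: a single occupied bin, flagged for downstream code
    breaks <- seq(rng[1] - 0.5, rng[2] + 0.5, length.out = n_bins + 1L)
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  counts <- tabulate(
    pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins)
  structure(list(breaks = breaks,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts, n = length(v),
                 bin_width = diff(breaks[1:2]),
                 spacing = spacing,
                 constant = sum(counts > 0) == 1L),
            class = "ct_histogram")
}

#' Cylindrical region-of-interest mask
#'
#' Selects voxels within `radius` of the device axis (z through x = y = 0),
#' the region the histogram analysis is restricted to.
#'
#' @param vol A volume object.
#' @param radius Radius (mm).
#' @return Logical array of `dim(vol$data)`.
#' @export
roi_cylinder <- function(vol, radius) {
  xc <- axis_coords(vol, 1)
  yc <- axis_coords(vol, 2)
  disc <- outer(xc^2, yc^2, "+") <= radius^2
  array(rep(disc, times = dim(vol$data)[3]), dim = dim(vol$data))
}

# EM for a 1-D Gaussian mixture on binned counts. Returns NULL on
# degeneracy so callers (AUTO selection) can skip that k.
em_binned <- function(mids, counts, k, bin_width, max_iter = 500,
                      tol = 1e-8, init_means = NULL) {
  n <- sum(counts)
  keep <- counts > 0
  x <- mids[keep]
  cts <- counts[keep]
  if (length(x) < k) return(NULL)
  mu <- if (!is.null(init_means)) init_means else {
    # quantile initialization on the empirical distribution
    cw <- cumsum(cts) / n
    stats::approx(cw, x, xout = (seq_len(k) - 0.5) / k, rule = 2)$y
  }
  mu <- sort(mu)
  sigma <- rep(max(stats::weighted.mean((x - stats::weighted.mean(x, cts))^2,
                                        cts)^0.5 / k, bin_width), k)
  w <- rep(1 / k, k)
  sd_floor <- bin_width / 2
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
                   numeric(length(x)))
    tot <- rowSums(dens)
    if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
    ll <- sum(cts * log(tot))
    resp <- dens / tot
    Nj <- colSums(cts * resp)
    if (any(Nj < 1e-12)) return(NULL)
    w <- Nj / n
    mu <- colSums(cts * resp * x) / Nj
    sigma <- sqrt(pmax(
      colSums(cts * resp * (x - rep(mu, each = length(x)))^2) / Nj +
        bin_width^2 / 12, sd_floor^2))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  ord <- order(mu)
  out <- list(weights = w[ord], means = mu[ord], sds = sigma[ord],
              loglik = ll, n = n, k = k)
  merge_close_components(out)
}

# Components below the unimodality limit (two Gaussians with |dmu| < 2 sigma
# do not form separate modes) are one peak that EM has split; merge them so a
# single-class histogram yields a single effective component. Material
# classes sit many sigma apart, far above the limit.
merge_close_components <- function(f) {
  repeat {
    if (f$k < 2L) return(f)
    gap <- diff(f$means)
    lim <- 2 * pmin(f$sds[-f$k], f$sds[-1])
    j <- which(gap < lim)[1]
    if (is.na(j)) return(f)
    w <- f$weights[j] + f$weights[j + 1]
    m <- (f$weights[j] * f$means[j] + f$weights[j + 1] * f$means[j + 1]) / w
    s2 <- (f$weights[j] * (f$sds[j]^2 + (f$means[j] - m)^2) +
           f$weights[j + 1] * (f$sds[j + 1]^2 + (f$means[j + 1] - m)^2)) / w
    keep <- setdiff(seq_len(f$k), j + 1)
    f$weights <- f$weights[keep]; f$means <- f$means[keep]
    f$sds <- f$sds[keep]
    f$weights[j] <- w; f$means[j] <- m; f$sds[j] <- sqrt(s2)
    f$k <- f$k - 1L
  }
}

#' Fit Gaussian peaks to an intensity histogram
#'
#' Maximum-likelihood Gaussian mixture on the binned counts (EM with a
#' Sheppard variance correction and a half-bin sd floor). `k = "auto"`
#' selects the component count in 2..5 by BIC. Components are assigned to
#' material classes by proximity of their fitted means to the material
#' model's class means (rank order is preserved because both are sorted).
#'
#' @param histogram A `ct_histogram`.
#' @param k Component count, or `"auto"`.
#' @param model A `material_model` used for class assignment.
#' @return An object of class `histogram_fit`: `components` (data.frame
#'   with weight, mean, sd, class), `k`, `bic`, `loglik`, `residual_rms`,
#'   `n`, `spacing`, plus the input histogram.
#' @export
fit_peaks <- function(histogram, k = "auto", model = material_model()) {
  stopifnot(inherits(histogram, "ct_histogram"))
  if (histogram$constant) {
    stop("degenerate histogram: constant image (single occupied bin)",
         call. = FALSE)
  }
  # EM is multi-start: quantile initialization finds the dominant peaks,
  # equal-spaced initialization finds low-weight peaks (a thin strut is a
  # tiny fraction of any region of interest); best log-likelihood wins
  fit_one <- function(kk) {
    rng <- range(histogram$mids[histogram$counts > 0])
    inits <- list(NULL,
                  seq(rng[1], rng[2], length.out = kk + 2L)[2:(kk + 1L)])
    fits <- Filter(Negate(is.null), lapply(inits, function(im) {
      em_binned(histogram$mids, histogram$counts, kk, histogram$bin_width,
                init_means = im)
    }))
    if (!length(fits)) return(NULL)
    fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  }
  if (identical(k, "auto") || identical(k, "AUTO")) {
    cands <- Filter(Negate(is.null), lapply(2:5, fit_one))
    if (!length(cands)) stop("peak fitting failed to converge", call. = FALSE)
    bics <- vapply(cands, function(f) {
      -2 * f$loglik + (3 * f$k - 1) * log(f$n)
    }, numeric(1))
    best <- cands[[which.min(bics)]]
  } else {
    kk <- check_count(k, "k", min = 1L)
    best <- fit_one(kk)
    if (is.null(best)) {
      # fewer distinct modes than requested: AUTO fallback
      return(fit_peaks(histogram, "auto", model))
    }
  }
  cls <- names(MATERIAL_CLASSES)[
    vapply(best$means, function(m) which.min(abs(model$means - m)),
           integer(1))]
  pred <- rowSums(vapply(seq_len(best$k), function(j) {
    best$weights[j] * stats::dnorm(histogram$mids, best$means[j],
                                   best$sds[j]) * histogram$bin_width
  }, numeric(length(histogram$mids))))
  obs <- histogram$counts / best$n
  structure(list(components = data.frame(weight = best$weights,
                                         mean = best$means, sd = best$sds,
                                         class = cls,
                                         stringsAsFactors = FALSE),
                 k = best$k, loglik = best$loglik,
                 bic = -2 * best$loglik + (3 * best$k - 1) * log(best$n),
                 residual_rms = sqrt(mean((obs - pred)^2)),
                 n = best$n, spacing = histogram$spacing,
                 histogram = histogram),
            class = "histogram_fit")
}

#' @export
print.histogram_fit <- function(x, ...) {
  cat(sprintf("histogram_fit: %d components on %d voxels (residual RMS %.2g)\n",
              x$k, x$n, x$residual_rms))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Remaining-volume estimate from a histogram fit
#'
#' Attributes volume to the magnesium-alloy peak by its mixture weight
#' (soft assignment): `mg_volume = weight(MG_ALLOY) * n_voxels * spacing^3`
#' over the voxels the histogram was computed from (restrict with a
#' [roi_cylinder()] mask when calling [compute_histogram()]). The ratio is
#' taken against the analytic as-manufactured scaffold volume.
#'
#' @param fit A `histogram_fit`.
#' @param graph The `design_graph` (supplies the denominator via
#'   [design_volume()]).
#' @param spacing Voxel spacing (mm); defaults to the spacing recorded in
#'   the fit.
#' @param attribution `"soft"` attributes volume by mixture weight;
#'   `"threshold"` hard-classifies histogram bins by maximum posterior (a
#'   threshold at the Gaussian intersections) and counts MG_ALLOY bins;
#'   `"midpoint"` counts bins between the tissue/alloy and alloy/dense
#'   class-mean midpoints (the half-maximum surface estimator, nearly
#'   unbiased under partial-volume blur for struts wider than ~2 PSF sigma).
#' @param model A `material_model`, used by `"midpoint"` when a class has
#'   no fitted component.
#' @return An object of class `volume_estimate`: `mg_volume`,
#'   `design_volume` (mm^3), `remaining_ratio`, `no_mg_component` flag.
#' @export
remaining_volume_ratio <- function(fit, graph, spacing = fit$spacing,
                                   attribution = c("soft", "threshold",
                                                   "midpoint"),
                                   model = material_model()) {
  stopifnot(inherits(fit, "histogram_fit"), inherits(graph, "design_graph"))
  attribution <- match.arg(attribution)
  check_scalar_num(spacing, "spacing", 0, strict_lower = TRUE)
  dv <- design_volume(graph)
  wmg <- switch(attribution,
    soft = sum(fit$components$weight[fit$components$class == "MG_ALLOY"]),
    threshold = {
      mids <- fit$histogram$mids
      dens <- vapply(seq_len(fit$k), function(j) {
        fit$components$weight[j] *
          stats::dnorm(mids, fit$components$mean[j], fit$components$sd[j])
      }, numeric(length(mids)))
      cls <- fit$components$class[max.col(dens, ties.method = "first")]
      sum(fit$histogram$counts[cls == "MG_ALLOY"]) / fit$n
    },
    midpoint = {
      # half-maximum rule: threshold midway between the tissue level and
      # the observed alloy plateau (the fitted alloy peak, which sits below
      # the calibrated class mean when the strut is only a few PSF sigma
      # wide); upper bound midway to the dense product level
      is_mg <- fit$components$class == "MG_ALLOY"
      plateau <- if (any(is_mg)) {
        stats::weighted.mean(fit$components$mean[is_mg],
                             fit$components$weight[is_mg])
      } else unname(model$means[["MG_ALLOY"]])
      lo <- (model$means[["TISSUE"]] + plateau) / 2
      hi <- (model$means[["MG_ALLOY"]] + model$means[["PRODUCT_DENSE"]]) / 2
      sel <- fit$histogram$mids > lo & fit$histogram$mids <= hi
      sum(fit$histogram$counts[sel]) / fit$n
    })
  no_mg <- wmg == 0
  if (no_mg) {
    warning("no MG_ALLOY-assigned component in fit; remaining ratio is 0")
  }
  mg_vol <- wmg * fit$n * spacing^3
  structure(list(mg_volume = mg_vol, design_volume = dv,
                 remaining_ratio = mg_vol / dv,
                 no_mg_component = no_mg),
            class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("volume_estimate: %.3f / %.3f mm^3 (remaining ratio %.3f)\n",
              x$mg_volume, x$design_volume, x$remaining_ratio))
  invisible(x)
}

#' Export a histogram fit to CSV
#' @param fit A `histogram_fit`.
#' @param components_csv,histogram_csv Output paths (`NULL` skips).
#' @return Invisibly, the paths written.
#' @export
export_fit <- function(fit, components_csv = NULL, histogram_csv = NULL) {
  stopifnot(inherits(fit, "histogram_fit"))
  out <- list()
  if (!is.null(components_csv)) {
    utils::write.csv(fit$components, components_csv, row.names = FALSE)
    out$components_csv <- components_csv
  }
  if (!is.null(histogram_csv)) {
    utils::write.csv(data.frame(mid = fit$histogram$mids,
                                count = fit$histogram$counts),
                     histogram_csv, row.names = FALSE)
    out$histogram_csv <- histogram_csv
  }
  invisible(out)
}
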