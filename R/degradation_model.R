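#' Isotropic strut degradation model
#'
#' A magnesium strut with rectangular cross-section `w x h` (mm) corrodes by
#' uniform recession of every exposed face at rate `k` (mm/month). Because a
#' strut is far longer than it is wide, end recession is negligible and the
#' remaining volume fraction equals the remaining cross-sectional area
#' fraction `(1 - 2kt/w)(1 - 2kt/h)`, clamped at zero once a dimension is
#' consumed. For the square strut this is `(1 - t/T)^2` with complete
#' degradation period `T = w / (2k)`.
#'
#' @param w Strut width (mm).
#' @param h Strut thickness (mm).
#' @param k Surface recession rate per exposed face (mm/month).
#' @return An object of class `degradation_params`.
#' @examples
#' p <- degradation_params(w = 0.1, h = 0.1, k = 0.0019115)
#' t_complete(p)
#' @export
degradation_params <- function(w = 0.1, h = w, k) {
  check_scalar_num(w, "w", 0, strict_lower = TRUE)
  check_scalar_num(h, "h", 0, strict_lower = TRUE)
  check_scalar_num(k, "k", 0)
  structure(list(w = w, h = h, k = k), class = "degradation_params")
}

#' Remaining cross-sectional area fraction at time t
#'
#' @param t Time (months), vectorized.
#' @param params A `degradation_params`.
#' @return Remaining area (= volume) fraction in `[0, 1]`.
#' @export
area_fraction <- function(t, params) {
  stopifnot(inherits(params, "degradation_params"), all(t >= 0))
  fw <- pmax(0, 1 - 2 * params$k * t / params$w)
  fh <- pmax(0, 1 - 2 * params$k * t / params$h)
  fw * fh
}

#' Recession rate from cross-sectional area loss at one month
#'
#' Inverts the area-fraction law at `t = 1` month. For a square strut of
#' side `s` the closed form is `k = s (1 - sqrt(1 - loss/100)) / 2`; for a
#' rectangular strut the smaller root of the quadratic is found numerically.
#'
#' @param loss Percent area loss at 1 month, in `[0, 100)` (100 allowed for
#'   the degenerate complete-at-one-month boundary).
#' @param w,h Strut cross-section (mm).
#' @return Rate `k` (mm/month).
#' @examples
#' k_from_loss_at_1M(5)    # the 5%-at-1-month scenario
#' @export
k_from_loss_at_1M <- function(loss, w = 0.1, h = w) {
  check_scalar_num(loss, "loss", 0, 100)
  check_scalar_num(w, "w", 0, strict_lower = TRUE)
  check_scalar_num(h, "h", 0, strict_lower = TRUE)
  target <- 1 - loss / 100
  if (loss == 0) return(0)
  if (isTRUE(all.equal(w, h))) {
    if (loss == 100) return(w / 2)
    return(w * (1 - sqrt(target)) / 2)
  }
  if (loss == 100) return(min(w, h) / 2)
  f <- function(k) (1 - 2 * k / w) * (1 - 2 * k / h) - target
  stats::uniroot(f, c(0, min(w, h) / 2), tol = 1e-14)$root
}

#' Complete and 50% degradation periods
#'
#' `t_complete` is when the thinner dimension is consumed,
#' `min(w, h) / (2k)`; `t50` solves `area_fraction = 0.5` (closed form
#' `t_complete * (1 - 1/sqrt(2))` for the square strut, bisection otherwise).
#' A zero recession rate yields an infinite lifetime, signalled with a
#' warning.
#'
#' @param params A `degradation_params`.
#' @return Time in months (`Inf` for `k = 0`).
#' @export
t_complete <- function(params) {
  stopifnot(inherits(params, "degradation_params"))
  if (params$k == 0) {
    warning("k = 0: strut never degrades (infinite lifetime)")
    return(Inf)
  }
  min(params$w, params$h) / (2 * params$k)
}

#' @rdname t_complete
#' @export
t50 <- function(params) {
  stopifnot(inherits(params, "degradation_params"))
  if (params$k == 0) {
    warning("k = 0: strut never degrades (infinite lifetime)")
    return(Inf)
  }
  tc <- min(params$w, params$h) / (2 * params$k)
  if (isTRUE(all.equal(params$w, params$h))) {
    return(tc * (1 - 1 / sqrt(2)))
  }
  stats::uniroot(function(t) area_fraction(t, params) - 0.5,
                 c(0, tc), tol = 1e-12)$root
}

#' Simulate remaining-volume scenario curves
#'
#' One curve per assumed percent area loss at one month: the rate is set by
#' [k_from_loss_at_1M()] and the remaining volume fraction evaluated on the
#' requested time grid. Defaults reproduce the 5% / 7.5% / 10% scenarios for
#' a 0.1 mm square strut.
#'
#' @param losses Percent area losses at 1 month.
#' @param times Evaluation times (months).
#' @param w,h Strut cross-section (mm).
#' @return A list of `scenario_curve` objects (fields `loss_at_1M`, `k`,
#'   `times`, `fractions`).
#' @export
simulate_scenarios <- function(losses = c(5, 7.5, 10),
                               times = seq(0, 30, by = 0.25),
                               w = 0.1, h = w) {
  stopifnot(length(losses) >= 1, all(times >= 0))
  lapply(losses, function(L) {
    k <- k_from_loss_at_1M(L, w, h)
    p <- degradation_params(w, h, k)
    structure(list(loss_at_1M = L, k = k, times = times,
                   fractions = area_fraction(times, p)),
              class = "scenario_curve")
  })
}

#' Fit the complete degradation period to remaining-volume observations
#'
#' Least-squares fit of the square-strut law `f(t) = max(0, 1 - t/T)^2` over
#' `T > 0` by bounded scalar minimization. Reports the fitted complete
#' degradation period, the implied 50% period `T (1 - 1/sqrt(2))`, and the
#' implied percent area loss at one month.
#'
#' @param observations A data.frame with columns `time` (months) and
#'   `fraction` (remaining volume fraction), or a two-column matrix.
#' @return An object of class `model_fit`: list with `T_fit`, `residual_ss`,
#'   `t50`, `t50_rounded` (whole months), `implied_loss_at_1M`,
#'   `observations`.
#' @examples
#' obs <- data.frame(time = c(1, 6, 12, 18),
#'                   fraction = pmax(0, 1 - c(1, 6, 12, 18) / 20)^2)
#' fit_T(obs)$T_fit
#' @export
fit_T <- function(observations) {
  obs <- as.data.frame(observations)
  if (!all(c("time", "fraction") %in% names(obs))) {
    names(obs)[1:2] <- c("time", "fraction")
  }
  obs <- obs[is.finite(obs$time) & is.finite(obs$fraction), , drop = FALSE]
  if (nrow(obs) < 2 || length(unique(obs$time)) < 2) {
    stop("fit_T requires at least 2 observations with distinct times",
         call. = FALSE)
  }
  if (all(obs$fraction <= 0)) {
    stop("all remaining fractions are zero: T is unidentifiable",
         call. = FALSE)
  }
  ss <- function(T) sum((pmax(0, 1 - obs$time / T)^2 - obs$fraction)^2)
  upper <- 50 * max(obs$time)
  opt <- stats::optimize(ss, c(1e-6, upper), tol = 1e-10)
  T_fit <- opt$minimum
  structure(list(T_fit = T_fit,
                 residual_ss = opt$objective,
                 t50 = T_fit * (1 - 1 / sqrt(2)),
                 t50_rounded = round(T_fit * (1 - 1 / sqrt(2))),
                 implied_loss_at_1M = 100 * (1 - pmax(0, 1 - 1 / T_fit)^2),
                 observations = obs),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf(
    "degradation model fit: T_complete = %.2f months, t50 = %.2f (~%d) months\n",
    x$T_fit, x$t50, x$t50_rounded))
  cat(sprintf("  implied loss at 1 month: %.2f%%; residual SS %.3g\n",
              x$implied_loss_at_1M, x$residual_ss))
  invisible(x)
}

#' Closest scenario to a reference degradation curve
#'
#' Among the candidate area-loss-at-1-month scenarios, returns the one whose
#' remaining-volume curve minimizes the sum of squared differences from the
#' reference curve `max(0, 1 - t/T)^2` at the given times. Ties go to the
#' smaller loss and are flagged in the `tie` attribute.
#'
#' @param reference A `model_fit` or a complete degradation period (months).
#' @param losses Candidate percent losses at 1 month.
#' @param times Comparison times (months).
#' @param w,h Strut cross-section (mm).
#' @return The winning loss (percent) with attributes `sums_of_squares` and
#'   `tie`.
#' @examples
#' best_scenario(23.5)   # 7.5
#' @export
best_scenario <- function(reference, losses = c(5, 7.5, 10),
                          times = c(1, 6, 12, 18), w = 0.1, h = w) {
  T_ref <- if (inherits(reference, "model_fit")) reference$T_fit else reference
  check_scalar_num(T_ref, "reference", 0, strict_lower = TRUE)
  g <- pmax(0, 1 - times / T_ref)^2
  curves <- simulate_scenarios(losses, times, w, h)
  ssq <- vapply(curves, function(cv) sum((cv$fractions - g)^2), numeric(1))
  names(ssq) <- as.character(losses)
  best <- which(ssq == min(ssq))
  tie <- length(best) > 1L
  if (tie) warning("tie between scenarios; returning the smaller loss")
  structure(losses[min(best)], sums_of_squares = ssq, tie = tie)
}
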