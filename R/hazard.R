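#' Kernel-smoothed hazard estimate
#'
#' Smooths the event-time increments of the Nelson-Aalen cumulative
#' hazard with an Epanechnikov kernel. Near the two edges of the
#' estimation window the kernel is replaced by a boundary-corrected
#' version (generalised jackknife: the interior kernel multiplied by the
#' linear factor that restores zeroth and first moment conditions on the
#' truncated support), so the estimate does not collapse at t = 0 or at
#' `max_time`.
#'
#' The bandwidth is global. The default, `max_time / 8`, is a pragmatic
#' smoothing level for trial-sized datasets and should be treated as a
#' display choice, not an optimum; pass `bandwidth` explicitly to probe
#' sensitivity.
#'
#' @param ds A `survival_dataset`.
#' @param bandwidth Kernel bandwidth in months, or `NULL` for the
#'   default `max_time / 8`.
#' @param max_time Right end of the estimation window in months. For
#'   data-cut screening this should be the cut's minimum follow-up, the
#'   region where the risk set is complete. Defaults to the maximum
#'   follow-up in `ds`.
#' @param grid_size Number of uniform grid points on `[0, max_time]`.
#' @return An object of class `hazard_curve`: list with `grid`,
#'   `hazard`, `bandwidth`, `max_time`.
#' @export
smoothed_hazard <- function(ds, bandwidth = NULL, max_time = NULL,
                            grid_size = 101L) {
  stopifnot(inherits(ds, "survival_dataset"))
  r <- ds$records
  if (sum(r$event) < 2) {
    stop("smoothed hazard estimation needs at least 2 events", call. = FALSE)
  }
  if (is.null(max_time)) max_time <- max(r$time)
  if (max_time > max(r$time)) {
    stop("max_time exceeds the maximum follow-up", call. = FALSE)
  }
  if (is.null(bandwidth)) bandwidth <- max_time / 8
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be positive", call. = FALSE)
  }
  km <- km_estimate(ds)
  # Nelson-Aalen increments d_i / n_i at distinct event times
  ev <- km$event_times
  dH <- km$n_events / km$at_risk
  inside <- ev <= max_time
  ev <- ev[inside]; dH <- dH[inside]
  grid <- seq(0, max_time, length.out = grid_size)
  hazard <- vapply(grid, function(t) {
    u <- (t - ev) / bandwidth
    w <- epanechnikov_boundary(u, t, bandwidth, max_time)
    sum(w * dH) / bandwidth
  }, numeric(1))
  hazard[hazard < 0] <- 0
  structure(list(grid = grid, hazard = hazard, bandwidth = bandwidth,
                 max_time = max_time, label = ds$label),
            class = "hazard_curve")
}

# Epanechnikov kernel with generalised-jackknife boundary correction.
# u are standardised distances (t - t_i)/b for evaluation point t; the
# correction is a linear-in-u multiplier K(u)(a2 - a1 u)/(a0 a2 - a1^2)
# with a_k the k-th truncated kernel moments over the support visible
# from t, which restores integral 1 and first moment 0 near the edges.
epanechnikov_boundary <- function(u, t, b, max_time) {
  K <- function(x) ifelse(abs(x) <= 1, 0.75 * (1 - x^2), 0)
  # visible standardised support at t: events lie in [0, max_time], so
  # u = (t - t_i)/b ranges over [(t - max_time)/b, t/b], clipped to [-1,1]
  lo <- max(-1, (t - max_time) / b)
  hi <- min(1, t / b)
  if (lo <= -1 + 1e-12 && hi >= 1 - 1e-12) {
    return(K(u))
  }
  mom <- function(k) {
    stats::integrate(function(x) x^k * K(x), lo, hi,
                     rel.tol = 1e-9)$value
  }
  a0 <- mom(0); a1 <- mom(1); a2 <- mom(2)
  den <- a0 * a2 - a1^2
  if (den <= 0) return(K(u) / max(a0, .Machine$double.eps))
  K(u) * (a2 - a1 * u) / den
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat(sprintf("Smoothed hazard curve: %d grid points on [0, %.3g], bandwidth %.3g months\n",
              length(x$grid), x$max_time, x$bandwidth))
  invisible(x)
}

#' Classify the shape of a smoothed hazard and screen model families
#'
#' Labels the curve as constant, monotone increasing, monotone
#' decreasing, or non-monotone from its cumulative swings: the curve has
#' a significant rise if some later grid value exceeds an earlier one by
#' more than `tolerance * max(hazard)`, and a significant fall in the
#' mirrored sense. Both present means non-monotone; one means monotone;
#' neither means constant. Working with cumulative swings rather than
#' point-to-point differences keeps small numerical wiggles from being
#' read as turning points while still detecting slow drifts that never
#' clear the tolerance in a single grid step.
#' The screening rule follows standard practice
#' for hazard-based model selection in single-arm extrapolation work:
#' a non-monotone hazard rules out the constant-hazard exponential and
#' the monotone-hazard Weibull and Gompertz families; a monotone hazard
#' rules out only the exponential; a constant hazard rules out nothing.
#'
#' @param curve A `hazard_curve`.
#' @param tolerance Relative tolerance for suppressing small changes
#'   (fraction of the curve maximum).
#' @return An object of class `hazard_shape`: list with `label` (one of
#'   `"constant"`, `"monotone_increasing"`, `"monotone_decreasing"`,
#'   `"non_monotone"`) and `rejected_families`.
#' @export
classify_hazard_shape <- function(curve, tolerance = 0.05) {
  stopifnot(inherits(curve, "hazard_curve"))
  h <- curve$hazard
  if (length(h) < 3) {
    stop("hazard shape classification needs at least 3 grid points",
         call. = FALSE)
  }
  hmax <- max(h)
  if (hmax <= 0) {
    stop("degenerate hazard curve: identically zero", call. = FALSE)
  }
  eps <- tolerance * hmax
  max_rise <- max(h - cummin(h))   # largest increase from an earlier value
  max_fall <- max(cummax(h) - h)   # largest decrease from an earlier value
  label <- if (max_rise > eps && max_fall > eps) {
    "non_monotone"
  } else if (max_rise > eps) {
    "monotone_increasing"
  } else if (max_fall > eps) {
    "monotone_decreasing"
  } else {
    "constant"
  }
  rejected <- switch(label,
    constant = character(0),
    monotone_increasing = "exponential",
    monotone_decreasing = "exponential",
    non_monotone = c("exponential", "weibull", "gompertz"))
  structure(list(label = label, rejected_families = rejected,
                 tolerance = tolerance), class = "hazard_shape")
}

#' @export
print.hazard_shape <- function(x, ...) {
  cat(sprintf("Hazard shape: %s; rejected families: %s\n", x$label,
              if (length(x$rejected_families))
                paste(x$rejected_families, collapse = ", ") else "none"))
  invisible(x)
}

#' Export a hazard curve as a data frame
#' @param curve A `hazard_curve`.
#' @return Data frame with columns `time`, `hazard`.
#' @export
hazard_as_data_frame <- function(curve) {
  data.frame(time = curve$grid, hazard = curve$hazard)
}
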