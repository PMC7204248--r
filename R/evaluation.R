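#' Information-criterion suite for a fitted model
#'
#' Computes the five goodness-of-fit statistics used to compare
#' parametric survival fits:
#' \deqn{-2LL = -2 \log L,\quad AIC = -2\log L + 2k,\quad
#'   AICc = AIC + \frac{2k^2 + 2k}{n - k - 1},}
#' \deqn{HQC = -2\log L + 2k\ln(\ln n),\quad BIC = -2\log L + k\ln n.}
#' At a trial-typical n = 88 the per-parameter penalties are about 2.0
#' (AIC), 3.0 (HQC) and 4.5 (BIC); AICc matters when n/k < 40.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size.
#' @return An object of class `ic_scores`: list with `minus2LL`, `AIC`,
#'   `AICc`, `HQC`, `BIC`, `k`, `n`.
#' @examples
#' information_criteria(-373.7 / 2, k = 2, n = 88)
#' @export
information_criteria <- function(loglik, k, n) {
  stopifnot(is.finite(loglik), k >= 0, n >= 1)
  if (n <= k + 1) {
    stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  }
  if (n <= exp(1)) {
    stop("HQC undefined: n must exceed e", call. = FALSE)
  }
  m2 <- -2 * loglik
  aic <- m2 + 2 * k
  structure(list(
    minus2LL = m2,
    AIC = aic,
    AICc = aic + (2 * k^2 + 2 * k) / (n - k - 1),
    HQC = m2 + 2 * k * log(log(n)),
    BIC = m2 + k * log(n),
    k = as.integer(k), n = as.integer(n)), class = "ic_scores")
}

#' @export
print.ic_scores <- function(x, ...) {
  cat(sprintf("-2LL %.1f | AIC %.1f | AICc %.1f | HQC %.1f | BIC %.1f  (k = %d, n = %d)\n",
              x$minus2LL, x$AIC, x$AICc, x$HQC, x$BIC, x$k, x$n))
  invisible(x)
}

ic_criteria <- c("minus2LL", "AIC", "AICc", "HQC", "BIC")

#' Rank models by an information criterion
#'
#' Sorts models ascending (lower is better), breaking ties by fewer
#' parameters and then by label, and annotates every model with its
#' score difference to the best model plus the usual rules of thumb:
#' `burnham_anderson_support` if the difference is at most 2 points
#' (substantial empirical support for the alternative),
#' `hilbe_no_difference` if at most 2.5 points, and
#' `hilbe_retain_small_n` if at most 6 points with `n <= 256`.
#'
#' @param scores Named list (or list of pairs) of `ic_scores`, names are
#'   model labels.
#' @param criterion One of `"AIC"`, `"AICc"`, `"HQC"`, `"BIC"`,
#'   `"minus2LL"` (the last is reported for context only; it ignores
#'   model complexity and is only meaningful across nested models).
#' @return Data frame sorted best-first with columns `label`, `score`,
#'   `k`, `delta`, `rank` and the three flag columns.
#' @export
rank_models <- function(scores, criterion = "AIC") {
  criterion <- match.arg(criterion, ic_criteria)
  if (length(scores) < 2) {
    stop("ranking needs at least two models", call. = FALSE)
  }
  labs <- names(scores)
  if (is.null(labs) || any(!nzchar(labs))) {
    stop("'scores' must be a named list of ic_scores", call. = FALSE)
  }
  ns <- vapply(scores, function(s) s$n, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("models fitted to different sample sizes are not comparable",
         call. = FALSE)
  }
  n <- ns[[1]]
  df <- data.frame(
    label = labs,
    score = vapply(scores, function(s) s[[criterion]], numeric(1)),
    k = vapply(scores, function(s) s$k, integer(1)),
    stringsAsFactors = FALSE)
  df <- df[order(df$score, df$k, df$label), , drop = FALSE]
  df$delta <- df$score - df$score[1]
  df$rank <- seq_len(nrow(df))
  df$burnham_anderson_support <- df$delta <= 2 & df$rank > 1
  df$hilbe_no_difference <- df$delta <= 2.5 & df$rank > 1
  df$hilbe_retain_small_n <- df$delta <= 6 & n <= 256 & df$rank > 1
  rownames(df) <- NULL
  df
}

#' Prediction accuracy of a fitted model against Kaplan-Meier curves
#'
#' Compares the model against the KM curve of the data cut it was
#' fitted to and against the KM curve of the latest available cut, via
#' (1) the survival point estimate (PE) at an anchor time and (2) the
#' restricted mean survival time over the same horizon. Differences are
#' model minus KM, so negative values mean the model underestimates
#' survival.
#'
#' @param m A `fitted_psm`.
#' @param km_fitted KM curve of the cut the model was fitted to.
#' @param km_latest KM curve of the latest cut.
#' @param anchor_fitted Anchor time (months) for the fitted cut,
#'   typically its minimum follow-up.
#' @param anchor_latest Anchor time (months) for the latest cut.
#' @param tau_latest RMST horizon (months) for the latest-cut
#'   comparison; defaults to `anchor_latest`.
#' @return An object of class `accuracy_report`: list with the model
#'   label and `pe_diff_fitted` / `pe_diff_latest` (percentage points),
#'   `rmst_diff_fitted` / `rmst_diff_latest` (months), and the
#'   timepoints used. Values carry full precision; `print` shows 1 dp.
#' @export
prediction_accuracy <- function(m, km_fitted, km_latest, anchor_fitted,
                                anchor_latest, tau_latest = anchor_latest) {
  stopifnot(inherits(m, "fitted_psm"))
  pe_f <- 100 * (model_survival(m, anchor_fitted) -
                   survival_at(km_fitted, anchor_fitted))
  pe_l <- 100 * (model_survival(m, anchor_latest) -
                   survival_at(km_latest, anchor_latest))
  rm_f <- model_rmst(m, anchor_fitted) - rmst_km(km_fitted, anchor_fitted)
  rm_l <- model_rmst(m, tau_latest) - rmst_km(km_latest, tau_latest)
  structure(list(model = model_name(m), label = m$label,
                 pe_diff_fitted = pe_f, pe_diff_latest = pe_l,
                 rmst_diff_fitted = rm_f, rmst_diff_latest = rm_l,
                 anchor_fitted = anchor_fitted,
                 anchor_latest = anchor_latest,
                 tau_latest = tau_latest),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("%s [%s]: PE diff %+.1f pp (fitted, %g mo) / %+.1f pp (latest, %g mo); RMST diff %+.1f / %+.1f months\n",
              x$model, x$label, x$pe_diff_fitted, x$anchor_fitted,
              x$pe_diff_latest, x$anchor_latest,
              x$rmst_diff_fitted, x$rmst_diff_latest))
  invisible(x)
}

#' Convert an RMST difference to life-years and QALYs
#'
#' A difference in restricted mean survival of `rmst_diff` months is
#' `rmst_diff / 12` (undiscounted) life-years; multiplying by a health
#' utility gives quality-adjusted life-years. E.g. underestimating RMST
#' by 1 month at a utility of 0.71 is about -0.08 life-years and -0.06
#' QALYs.
#'
#' @param rmst_diff RMST difference in months.
#' @param utility Health-state utility in `[0, 1]`.
#' @return List with `life_years` and `qalys` (full precision; round to
#'   2 dp for reporting).
#' @export
lifeyear_impact <- function(rmst_diff, utility) {
  stopifnot(is.finite(rmst_diff), utility >= 0, utility <= 1)
  ly <- rmst_diff / 12
  list(life_years = ly, qalys = utility * ly)
}
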