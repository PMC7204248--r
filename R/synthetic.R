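# Synthetic single-arm trial generator. Emulates the situation the
# package is built for: an immuno-oncology trial whose overall-survival
# curve plateaus (a fraction of long-term survivors), read out at
# several successive database locks. True survival is a two-component
# mixture — a short-term Weibull component and a low-rate exponential
# long-term component. The mixture is a data-generating device only;
# the fitting side of the package deliberately contains no cure/mixture
# models.

#' Default Kaplan-Meier anchor points for generator calibration
#'
#' Published summary estimates of overall survival for the motivating
#' single-arm trial (n = 88, metastatic Merkel cell carcinoma,
#' avelumab): S(12) = 51.8%, S(18) = 39.9%, S(24) = 35.8%,
#' S(30) = 33.4%, S(36) = 32.1%, with a 36-month restricted mean
#' survival time of 17.5 months.
#'
#' @return List with `anchors` (data frame `t`, `S`) and `rmst_target`
#'   (list `tau`, `rmst`).
#' @export
default_anchors <- function() {
  list(anchors = data.frame(t = c(12, 18, 24, 30, 36),
                            S = c(0.518, 0.399, 0.358, 0.334, 0.321)),
       rmst_target = list(tau = 36, rmst = 17.5))
}

#' Generator parameters for the synthetic trial
#'
#' Defaults are the output of [calibrate_generator()] on
#' [default_anchors()]: a plateau mixture matched to the published
#' survival summaries of the motivating trial. `lock_offsets` are months
#' of minimum follow-up, i.e. each database lock happens that many
#' months after the last patient enrolled.
#'
#' @param pi Long-term (plateau) fraction in (0, 1].
#' @param short Short-term component: list with `family` (`"weibull"`)
#'   and `params` (shape, scale).
#' @param long Long-term component: list with `family` (`"exponential"`)
#'   and `params` (rate per month).
#' @param accrual_window Accrual duration in months (entries are uniform
#'   over it).
#' @param dropout_rate Exponential dropout (non-administrative
#'   censoring) rate per month; 0 disables dropout.
#' @param n Number of patients.
#' @param lock_offsets Months of minimum follow-up for the successive
#'   database locks.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(pi = 0.315514,
                             short = list(family = "weibull",
                                          params = c(1.209174, 9.997361)),
                             long = list(family = "exponential",
                                         params = 1.1e-10),
                             accrual_window = 12,
                             dropout_rate = 0.002,
                             n = 88,
                             lock_offsets = c(12, 18, 24, 36)) {
  stopifnot(pi > 0, pi <= 1, accrual_window > 0, dropout_rate >= 0,
            n >= 1, all(diff(lock_offsets) > 0))
  structure(list(pi = pi, short = short, long = long,
                 accrual_window = accrual_window,
                 dropout_rate = dropout_rate, n = as.integer(n),
                 lock_offsets = lock_offsets),
            class = "generator_params")
}

#' @export
print.generator_params <- function(x, ...) {
  cat(sprintf("Synthetic trial generator: n = %d, plateau fraction %.3f\n",
              x$n, x$pi))
  cat(sprintf("  short-term %s(%s), long-term %s(%s)\n",
              x$short$family, paste(signif(x$short$params, 4), collapse = ", "),
              x$long$family, paste(signif(x$long$params, 4), collapse = ", ")))
  cat(sprintf("  accrual %g months, dropout %.4g/month, locks at +%s months\n",
              x$accrual_window, x$dropout_rate,
              paste(x$lock_offsets, collapse = "/")))
  invisible(x)
}

component_survival <- function(comp, t) {
  family_survival(comp$family, comp$params, t)
}

#' True survivor function of the generator mixture
#'
#' `S(t) = pi * S_long(t) + (1 - pi) * S_short(t)`, exactly.
#'
#' @param p A `generator_params`.
#' @param t Time(s) in months, `>= 0`.
#' @return Survival probabilities.
#' @export
true_survival <- function(p, t) {
  stopifnot(inherits(p, "generator_params"), all(t >= 0))
  p$pi * component_survival(p$long, t) +
    (1 - p$pi) * component_survival(p$short, t)
}

#' True restricted mean survival time of the generator mixture
#'
#' @param p A `generator_params`.
#' @param tau Horizon in months.
#' @return RMST in months, by adaptive quadrature.
#' @export
true_rmst <- function(p, tau) {
  stopifnot(inherits(p, "generator_params"), tau >= 0)
  if (tau == 0) return(0)
  stats::integrate(function(t) true_survival(p, t), 0, tau,
                   abs.tol = 1e-8)$value
}

#' Calibrate the generator mixture to survival anchor points
#'
#' Least-squares fit of the mixture parameters (plateau fraction,
#' Weibull shape and scale of the short-term component, exponential rate
#' of the long-term component) to a set of `(t, S)` anchor points plus
#' an RMST constraint. The RMST residual enters in survival-equivalent
#' units, i.e. `(RMST(tau) - target)/tau`, so it carries weight
#' comparable to one anchor. Optimisation runs from a fixed multistart
#' grid and is fully deterministic.
#'
#' @param anchors Data frame with columns `t`, `S`; at least 4 rows.
#' @param rmst_target List with `tau` and `rmst`, or `NULL` to calibrate
#'   on anchors only.
#' @param ... Further arguments passed to [generator_params()] (e.g.
#'   `n`, `dropout_rate`).
#' @return A `generator_params` with attribute `"residuals"` holding the
#'   anchor residuals (fitted minus target survival) and
#'   `"rmst_residual"`.
#' @export
calibrate_generator <- function(anchors = default_anchors()$anchors,
                                rmst_target = default_anchors()$rmst_target,
                                ...) {
  stopifnot(is.data.frame(anchors), nrow(anchors) >= 4,
            all(c("t", "S") %in% names(anchors)))
  mix_surv <- function(th, t) {
    pi <- stats::plogis(th[1])
    pi * exp(-exp(th[4]) * t) +
      (1 - pi) * exp(-(t / exp(th[3]))^exp(th[2]))
  }
  objective <- function(th) {
    res <- mix_surv(th, anchors$t) - anchors$S
    val <- sum(res^2)
    if (!is.null(rmst_target)) {
      rm <- tryCatch(
        stats::integrate(function(t) mix_surv(th, t), 0, rmst_target$tau,
                         abs.tol = 1e-8)$value,
        error = function(e) NA_real_)
      if (!is.finite(rm)) return(1e10)
      val <- val + ((rm - rmst_target$rmst) / rmst_target$tau)^2
    }
    val
  }
  starts <- expand.grid(pi = c(0.2, 0.35, 0.5),
                        shape = c(1, 1.5),
                        scale = c(8, 15),
                        rate = c(0.002, 0.01))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- c(stats::qlogis(starts$pi[i]), log(starts$shape[i]),
             log(starts$scale[i]), log(starts$rate[i]))
    fit <- tryCatch({
      f1 <- stats::optim(th0, objective, method = "Nelder-Mead",
                         control = list(maxit = 1000, reltol = 1e-12))
      stats::optim(f1$par, objective, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-12))
    }, error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("generator calibration failed to converge", call. = FALSE)
  }
  th <- best$par
  p <- generator_params(pi = stats::plogis(th[1]),
                        short = list(family = "weibull",
                                     params = exp(th[2:3])),
                        long = list(family = "exponential",
                                    params = exp(th[4])),
                        ...)
  attr(p, "residuals") <- true_survival(p, anchors$t) - anchors$S
  attr(p, "rmst_residual") <- if (is.null(rmst_target)) NA_real_ else
    true_rmst(p, rmst_target$tau) - rmst_target$rmst
  p
}

# inverse-transform draw from a mixture component
component_draw <- function(comp, u) {
  switch(comp$family,
    weibull = stats::qweibull(u, shape = comp$params[1],
                              scale = comp$params[2]),
    exponential = stats::qexp(u, rate = comp$params[1]),
    stop(sprintf("unsupported generator component '%s'", comp$family),
         call. = FALSE))
}

#' Simulate a synthetic single-arm trial with database locks
#'
#' Draws staggered enrolments uniform over the accrual window, latent
#' death times by inverse transform from the plateau mixture (component
#' membership Bernoulli(`pi`)), and optional exponential dropout. Each
#' database lock is placed `lock_offsets[j]` months after the last
#' enrolment, so the minimum follow-up of cut `j` equals
#' `lock_offsets[j]` exactly; per-cut datasets are produced with
#' [apply_data_cut()]. Fully reproducible from `seed`.
#'
#' @param p A `generator_params`.
#' @param seed Integer seed.
#' @return List with `calendar` (the uncut `survival_dataset` with entry
#'   times; `time` is the latent-to-dropout observation time from
#'   entry), `cuts` (named list of per-cut datasets, labels
#'   `"<offset>mo"`), and `locks` (calendar lock times).
#' @export
simulate_trial <- function(p, seed = 1L) {
  stopifnot(inherits(p, "generator_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  n <- p$n
  entry <- stats::runif(n, 0, p$accrual_window)
  member_long <- stats::runif(n) < p$pi
  u <- stats::runif(n)
  death <- ifelse(member_long,
                  component_draw(p$long, u),
                  component_draw(p$short, u))
  death <- pmax(death, 1e-9)
  if (p$dropout_rate > 0) {
    drop_t <- stats::rexp(n, rate = p$dropout_rate)
    time <- pmin(death, drop_t)
    event <- as.numeric(death <= drop_t)
  } else {
    time <- death
    event <- rep(1, n)
  }
  calendar <- survival_dataset(time = time, event = event, entry = entry,
                               label = "calendar")
  locks <- max(entry) + p$lock_offsets
  cuts <- lapply(seq_along(locks), function(j) {
    apply_data_cut(calendar,
                   data_cut_spec(locks[j],
                                 label = sprintf("%gmo", p$lock_offsets[j])))
  })
  names(cuts) <- vapply(cuts, function(d) d$label, character(1))
  list(calendar = calendar, cuts = cuts, locks = locks)
}
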