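# Survival, density and log-density for the six standard families, in
# their natural parameterisations:
#   exponential  rate
#   weibull      shape, scale
#   gompertz     shape (any sign), rate > 0        h(t) = rate * exp(shape t)
#   lognormal    meanlog, sdlog
#   loglogistic  shape, scale                      S(t) = 1/(1 + (t/scale)^shape)
#   gengamma     mu, sigma > 0, Q                  Prentice form; Q=0 lognormal,
#                                                  Q=1 Weibull, Q=sigma gamma
# The generalized gamma follows the (mu, sigma, Q) convention in which
# the lognormal is the Q -> 0 limit.

psm_families <- c("exponential", "weibull", "gompertz", "lognormal",
                  "loglogistic", "gengamma")

#' Standard parametric family names
#'
#' @return Character vector of the six supported standard families.
#' @export
standard_families <- function() psm_families

family_npar <- function(family) {
  switch(family,
         exponential = 1L,
         weibull = 2L, gompertz = 2L, lognormal = 2L, loglogistic = 2L,
         gengamma = 3L,
         stop(sprintf("unknown family '%s'", family), call. = FALSE))
}

check_params <- function(family, params) {
  if (length(params) != family_npar(family) || any(!is.finite(params))) {
    stop(sprintf("'%s' expects %d finite parameters", family,
                 family_npar(family)), call. = FALSE)
  }
  ok <- switch(family,
    exponential = params[1] > 0,
    weibull = all(params > 0),
    gompertz = params[2] > 0,
    lognormal = params[2] > 0,
    loglogistic = all(params > 0),
    gengamma = params[2] > 0)
  if (!ok) {
    stop(sprintf("parameters outside the domain of '%s'", family),
         call. = FALSE)
  }
  invisible(TRUE)
}

# survivor function; vectorised over t >= 0
family_survival <- function(family, params, t) {
  switch(family,
    exponential = exp(-params[1] * t),
    weibull = stats::pweibull(t, shape = params[1], scale = params[2],
                              lower.tail = FALSE),
    gompertz = exp(-gompertz_cumhaz(t, params[1], params[2])),
    lognormal = stats::plnorm(t, meanlog = params[1], sdlog = params[2],
                              lower.tail = FALSE),
    loglogistic = 1 / (1 + (t / params[2])^params[1]),
    gengamma = gengamma_survival(t, params[1], params[2], params[3]))
}

# log density; vectorised over t > 0
family_logdens <- function(family, params, t) {
  switch(family,
    exponential = log(params[1]) - params[1] * t,
    weibull = stats::dweibull(t, shape = params[1], scale = params[2],
                              log = TRUE),
    gompertz = log(params[2]) + params[1] * t -
      gompertz_cumhaz(t, params[1], params[2]),
    lognormal = stats::dlnorm(t, meanlog = params[1], sdlog = params[2],
                              log = TRUE),
    loglogistic = {
      p <- params[1]; s <- params[2]
      log(p) - log(s) + (p - 1) * (log(t) - log(s)) -
        2 * log1p((t / s)^p)
    },
    gengamma = gengamma_logdens(t, params[1], params[2], params[3]))
}

# Gompertz cumulative hazard H(t) = rate/shape (exp(shape t) - 1),
# continuous at shape -> 0 (exponential). Negative shape gives a
# defective distribution with plateau exp(-rate/|shape|).
gompertz_cumhaz <- function(t, shape, rate) {
  if (abs(shape) < 1e-12) rate * t else rate / shape * expm1(shape * t)
}

gengamma_survival <- function(t, mu, sigma, Q) {
  if (abs(Q) < 1e-8) {
    return(stats::plnorm(t, meanlog = mu, sdlog = sigma,
                         lower.tail = FALSE))
  }
  w <- (log(t) - mu) / sigma
  gam <- Q^-2
  expnu <- exp(Q * w) * gam
  if (Q > 0) {
    stats::pgamma(expnu, shape = gam, lower.tail = FALSE)
  } else {
    stats::pgamma(expnu, shape = gam, lower.tail = TRUE)
  }
}

gengamma_logdens <- function(t, mu, sigma, Q) {
  if (abs(Q) < 1e-8) {
    return(stats::dlnorm(t, meanlog = mu, sdlog = sigma, log = TRUE))
  }
  w <- (log(t) - mu) / sigma
  gam <- Q^-2
  log(abs(Q)) + gam * log(gam) - lgamma(gam) +
    gam * (Q * w - exp(Q * w)) - log(sigma) - log(t)
}

#' Right-censored log-likelihood of a standard parametric family
#'
#' Sum of log densities over events plus log survivor values over
#' censored observations.
#'
#' @param family Family name, one of [standard_families()].
#' @param params Numeric parameter vector in the family's natural
#'   parameterisation (see Details of [fit_mle()]).
#' @param ds A `survival_dataset`.
#' @return The log-likelihood (a scalar).
#' @examples
#' ds <- survival_dataset(time = 1:4, event = rep(1, 4))
#' loglik("exponential", 0.4, ds)  # 4*log(0.4) - 0.4*10
#' @export
loglik <- function(family, params, ds) {
  stopifnot(inherits(ds, "survival_dataset"))
  family <- match.arg(family, psm_families)
  check_params(family, params)
  r <- ds$records
  ev <- r$event == 1
  ll <- 0
  if (any(ev)) ll <- ll + sum(family_logdens(family, params, r$time[ev]))
  if (any(!ev)) {
    S <- family_survival(family, params, r$time[!ev])
    ll <- ll + sum(log(S))
  }
  ll
}
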