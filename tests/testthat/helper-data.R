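# shared fixtures, all generated in code

toy_dataset <- function() {
  survival_dataset(time = c(3, 5, 7, 9), event = c(1, 0, 1, 0))
}

# random right-censored dataset with Weibull deaths and uniform censoring
random_censored_dataset <- function(n, seed) {
  set.seed(seed)
  shape <- stats::runif(1, 0.8, 1.6)
  scale <- stats::runif(1, 5, 20)
  death <- stats::rweibull(n, shape = shape, scale = scale)
  cens <- stats::runif(n, 2, 30)
  survival_dataset(time = pmax(pmin(death, cens), 1e-6),
                   event = as.numeric(death <= cens))
}

# dataset from a named family with administrative censoring at cens_time
family_dataset <- function(family, params, n, seed, cens_time = Inf) {
  set.seed(seed)
  death <- switch(family,
    exponential = stats::rexp(n, rate = params[1]),
    weibull = stats::rweibull(n, shape = params[1], scale = params[2]),
    lognormal = stats::rlnorm(n, meanlog = params[1], sdlog = params[2]),
    stop("unsupported family in helper"))
  time <- pmin(death, cens_time)
  survival_dataset(time = pmax(time, 1e-9),
                   event = as.numeric(death <= cens_time))
}

make_hazard_curve <- function(grid, hazard, bandwidth = 1) {
  structure(list(grid = grid, hazard = hazard, bandwidth = bandwidth,
                 max_time = max(grid), label = ""),
            class = "hazard_curve")
}
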