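test_that("log-likelihood matches closed forms and limiting identities", {
  ds <- survival_dataset(time = 1:4, event = rep(1, 4))
  expect_equal(loglik("exponential", 0.4, ds), 4 * log(0.4) - 0.4 * 10)

  # a censored observation at tiny t contributes ~ log S(0) = 0
  base <- loglik("weibull", c(1.3, 10), ds)
  ds_plus <- survival_dataset(time = c(1:4, 1e-12), event = c(rep(1, 4), 0))
  expect_equal(loglik("weibull", c(1.3, 10), ds_plus), base,
               tolerance = 1e-10)

  # Weibull with shape 1 is the exponential
  ds2 <- random_censored_dataset(50, seed = 5)
  expect_equal(loglik("weibull", c(1, 1 / 0.23), ds2),
               loglik("exponential", 0.23, ds2), tolerance = 1e-12)

  expect_error(loglik("weibull", c(-1, 2), ds), "domain")
  expect_error(loglik("lognormal", c(0, -1), ds), "domain")
})

test_that("exponential MLE equals the closed form events / total time", {
  ds <- survival_dataset(time = 1:4, event = rep(1, 4))
  fit <- fit_mle("exponential", ds)
  expect_equal(fit$params, 0.4, tolerance = 1e-7)
  expect_equal(fit$k, 1L)
  expect_true(fit$converged)
  expect_error(fit_mle("exponential",
                       survival_dataset(time = c(1, 2), event = c(0, 0))),
               "at least one event")
})

test_that("MLE recovers Weibull and lognormal parameters at n = 5000", {
  # ~20% administrative censoring: censor where true survival is 0.2
  cw <- 15 * (-log(0.2))^(1 / 1.2)
  dsw <- family_dataset("weibull", c(1.2, 15), 5000, seed = 31,
                        cens_time = cw)
  fw <- fit_mle("weibull", dsw)
  expect_lt(abs(fw$params[1] - 1.2) / 1.2, 0.05)
  expect_lt(abs(fw$params[2] - 15) / 15, 0.05)

  cl <- stats::qlnorm(0.8, 2, 0.8)
  dsl <- family_dataset("lognormal", c(2, 0.8), 5000, seed = 32,
                        cens_time = cl)
  fl <- fit_mle("lognormal", dsl)
  expect_lt(abs(fl$params[1] - 2) / 2, 0.05)
  expect_lt(abs(fl$params[2] - 0.8) / 0.8, 0.05)
})

test_that("all six families match flexsurv log-likelihoods to 1e-4", {
  skip_if_not_installed("flexsurv")
  dists <- c(exponential = "exp", weibull = "weibull",
             gompertz = "gompertz", lognormal = "lnorm",
             loglogistic = "llogis", gengamma = "gengamma")
  for (seed in 1:20) {
    ds <- random_censored_dataset(120, seed = seed)
    for (fam in names(dists)) {
      mine <- fit_mle(fam, ds)
      ref <- flexsurv::flexsurvreg(
        survival::Surv(ds$records$time, ds$records$event) ~ 1,
        dist = dists[[fam]])
      ll_ref <- as.numeric(stats::logLik(ref))
      # likelihood formulas agree pointwise at the reference optimum
      expect_equal(loglik(fam, ref$res[, "est"], ds), ll_ref,
                   tolerance = 1e-6,
                   label = sprintf("%s loglik formula (seed %d)", fam, seed))
      if (fam == "gengamma") {
        # the generalized-gamma likelihood is multimodal: optimisers may
        # settle in different basins, but ours must never do worse
        expect_gte(mine$loglik, ll_ref - 1e-4)
      } else {
        expect_equal(mine$loglik, ll_ref, tolerance = 1e-4,
                     label = sprintf("%s loglik (seed %d)", fam, seed))
      }
    }
  }
})

test_that("fitted parameters are a local maximum of the likelihood", {
  for (seed in 1:6) {
    ds <- random_censored_dataset(100, seed = 100 + seed)
    for (fam in standard_families()) {
      fit <- fit_mle(fam, ds)
      set.seed(seed)
      for (i in 1:64) {
        pert <- fit$params * exp(stats::rnorm(fit$k, 0, 0.05))
        if (fam == "gompertz") pert[1] <- fit$params[1] + stats::rnorm(1, 0, 0.01)
        if (fam == "gengamma") {
          pert[1] <- fit$params[1] + stats::rnorm(1, 0, 0.05)
          pert[3] <- fit$params[3] + stats::rnorm(1, 0, 0.05)
        }
        ll <- tryCatch(loglik(fam, pert, ds), error = function(e) -Inf)
        expect_lte(ll, fit$loglik + 1e-6)
      }
    }
  }
})

test_that("nesting: richer families attain no worse log-likelihoods", {
  for (seed in 1:8) {
    ds <- random_censored_dataset(90, seed = 200 + seed)
    ll <- vapply(c("exponential", "weibull", "lognormal", "gengamma"),
                 function(f) fit_mle(f, ds)$loglik, numeric(1))
    expect_gte(ll[["weibull"]], ll[["exponential"]] - 1e-5)
    expect_gte(ll[["gengamma"]], ll[["weibull"]] - 1e-4)
    expect_gte(ll[["gengamma"]], ll[["lognormal"]] - 1e-4)
  }
})

test_that("model survival evaluates closed forms and limits", {
  ds <- survival_dataset(time = 1:4, event = rep(1, 4))
  fe <- fit_mle("exponential", ds)
  fe$params <- 0.1
  expect_equal(model_survival(fe, 10), exp(-1))
  expect_equal(model_survival(fe, 0), 1)

  # generalized gamma at the lognormal limit
  t <- c(0.5, 2, 10, 40)
  expect_equal(psmcuts:::family_survival("gengamma", c(2, 0.8, 0), t),
               stats::plnorm(t, 2, 0.8, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(psmcuts:::family_survival("gengamma", c(2, 0.8, 1e-5), t),
               stats::plnorm(t, 2, 0.8, lower.tail = FALSE),
               tolerance = 1e-4)
  # and at the Weibull special case Q = 1, sigma = 1/shape
  expect_equal(psmcuts:::family_survival("gengamma", c(log(15), 1 / 1.2, 1), t),
               stats::pweibull(t, 1.2, 15, lower.tail = FALSE),
               tolerance = 1e-8)

  # survivor functions decrease in t and vanish at infinity
  for (fam in standard_families()) {
    params <- switch(fam, exponential = 0.1, weibull = c(1.3, 12),
                     gompertz = c(0.05, 0.02), lognormal = c(2, 0.7),
                     loglogistic = c(1.5, 10), gengamma = c(2, 0.7, 0.5))
    tt <- c(seq(0.01, 500, length.out = 400), 5000)
    S <- psmcuts:::family_survival(fam, params, tt)
    expect_true(all(diff(S) <= 1e-12), label = fam)
    expect_lt(S[length(S)], 1e-3)   # heavy loglogistic tail needs t = 5000
  }
})

test_that("model RMST matches quadrature-free closed forms", {
  fe <- fit_mle("exponential", survival_dataset(time = 1:4, event = rep(1, 4)))
  fe$params <- 0.1
  expect_equal(model_rmst(fe, 36), (1 - exp(-0.1 * 36)) / 0.1,
               tolerance = 1e-6)
  expect_equal(model_rmst(fe, 0), 0)

  # RMST is bounded by the horizon for any fitted model
  ds <- random_censored_dataset(60, seed = 77)
  for (fam in c("weibull", "gompertz", "loglogistic")) {
    expect_lte(model_rmst(fit_mle(fam, ds), 24), 24)
  }
})

test_that("Gompertz with negative shape plateaus but keeps finite RMST", {
  f <- fit_mle("gompertz", random_censored_dataset(60, seed = 88))
  f$params <- c(-0.08, 0.05)
  plateau <- exp(-0.05 / 0.08)
  expect_equal(model_survival(f, 1e6), plateau, tolerance = 1e-10)
  expect_true(is.finite(model_rmst(f, 120)))
})
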