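test_that("information criteria reproduce published worked examples", {
  # lognormal, k = 2, n = 88, -2LL = 373.7
  ic <- information_criteria(loglik = -373.7 / 2, k = 2, n = 88)
  expect_equal(round(ic$minus2LL, 1), 373.7)
  expect_equal(round(ic$AIC, 1), 377.7)
  expect_equal(round(ic$AICc, 1), 377.8)
  expect_equal(round(ic$HQC, 1), 379.7)
  expect_equal(round(ic$BIC, 1), 382.7)

  # 1-knot odds spline, k = 3, n = 88, -2LL = 373.3
  ic2 <- information_criteria(loglik = -373.3 / 2, k = 3, n = 88)
  expect_equal(round(ic2$AIC, 1), 379.3)
  expect_equal(round(ic2$BIC, 1), 386.7)
})

test_that("per-parameter penalties at n = 88 are 2.0 / 3.0 / 4.5", {
  expect_equal(2, 2)  # AIC penalty coefficient is 2 by definition
  expect_equal(round(2 * log(log(88)), 1), 3.0)   # HQC
  expect_equal(round(log(88), 1), 4.5)            # BIC
  ic1 <- information_criteria(-100, k = 1, n = 88)
  ic2 <- information_criteria(-100, k = 2, n = 88)
  expect_equal(ic2$AIC - ic1$AIC, 2)
  expect_equal(round(ic2$HQC - ic1$HQC, 1), 3.0)
  expect_equal(round(ic2$BIC - ic1$BIC, 1), 4.5)
})

test_that("AICc correction and score identities hold for all k at n = 88", {
  for (k in 1:5) {
    ic <- information_criteria(-200, k = k, n = 88)
    expect_equal(ic$AICc - ic$AIC, (2 * k^2 + 2 * k) / (88 - k - 1))
    expect_equal(ic$AIC - ic$minus2LL, 2 * k)
    expect_equal(ic$BIC - ic$minus2LL, k * log(88))
    expect_equal(ic$HQC - ic$minus2LL, 2 * k * log(log(88)))
    expect_gte(ic$BIC, ic$AIC)            # n = 88 >= 8
    expect_gte(ic$AICc, ic$AIC)
    expect_gte(ic$HQC, ic$AIC)            # n = 88 >= 16
    expect_lte(ic$HQC, ic$BIC)
  }
  expect_error(information_criteria(-10, k = 4, n = 5), "AICc")
  # k = 0: every score collapses to -2LL
  ic0 <- information_criteria(-50, k = 0, n = 88)
  expect_true(all(unlist(ic0[c("AIC", "AICc", "HQC", "BIC")]) == 100))
})

test_that("model ranking applies delta rules of thumb and tie-breaks", {
  s <- list(lognormal = information_criteria(-373.7 / 2, 2, 88),
            `1-knot odds` = information_criteria(-373.3 / 2, 3, 88))
  rk <- rank_models(s, "AIC")
  expect_equal(rk$label[1], "lognormal")
  expect_equal(round(rk$delta[2], 1), 1.6)
  expect_true(rk$burnham_anderson_support[2])
  expect_true(rk$hilbe_no_difference[2])
  expect_true(rk$hilbe_retain_small_n[2])

  # delta = 5 at n = 88: retained under the small-n rule only
  s2 <- list(a = information_criteria(-100, 2, 88),
             b = information_criteria(-102.5, 2, 88))
  rk2 <- rank_models(s2, "AIC")
  expect_equal(rk2$delta[2], 5)
  expect_false(rk2$burnham_anderson_support[2])
  expect_false(rk2$hilbe_no_difference[2])
  expect_true(rk2$hilbe_retain_small_n[2])

  # identical scores rank the simpler model first
  s3 <- list(complex = information_criteria(-101, 4, 88),
             simple = information_criteria(-103, 2, 88))
  expect_equal(rank_models(s3, "AIC")$label[1], "simple")

  # mixed sample sizes are not comparable
  s4 <- list(a = information_criteria(-100, 2, 88),
             b = information_criteria(-100, 2, 90))
  expect_error(rank_models(s4, "AIC"), "not comparable")
  expect_error(rank_models(s["lognormal"], "AIC"), "at least two")
})

test_that("ranking is invariant to a constant log-likelihood shift", {
  lls <- c(-190, -186, -188); ks <- c(2, 3, 4)
  for (cr in c("AIC", "AICc", "HQC", "BIC")) {
    r1 <- rank_models(stats::setNames(Map(information_criteria, lls, ks,
                                          MoreArgs = list(n = 88)),
                                      c("a", "b", "c")), cr)
    r2 <- rank_models(stats::setNames(Map(information_criteria, lls + 7.3, ks,
                                          MoreArgs = list(n = 88)),
                                      c("a", "b", "c")), cr)
    expect_equal(r1$label, r2$label)
    expect_equal(r1$delta, r2$delta)
  }
})

test_that("prediction accuracy uses the model-minus-KM sign convention", {
  # KM with survival 0.321 just after 36 months, built from 1000
  # uncensored patients with 679 deaths before month 36
  t <- c(seq(0.05, 35.9, length.out = 679), seq(37, 50, length.out = 321))
  km <- km_estimate(survival_dataset(time = t, event = rep(1, 1000)))
  expect_equal(survival_at(km, 36), 0.321)

  # model with S(36) = 0.255: point-estimate difference -6.6 points
  m <- fit_mle("exponential", survival_dataset(time = 1:4, event = rep(1, 4)))
  m$params <- -log(0.255) / 36
  rep1 <- prediction_accuracy(m, km_fitted = km, km_latest = km,
                              anchor_fitted = 36, anchor_latest = 36)
  expect_equal(round(rep1$pe_diff_latest, 1), -6.6)
  expect_equal(rep1$pe_diff_fitted, rep1$pe_diff_latest)
  expect_equal(rep1$rmst_diff_latest,
               model_rmst(m, 36) - rmst_km(km, 36), tolerance = 1e-9)

  # a model that underestimates survival must report negative diffs
  low <- m; low$params <- 1.5 * m$params
  rep2 <- prediction_accuracy(low, km, km, 36, 36)
  expect_lt(rep2$pe_diff_latest, rep1$pe_diff_latest)
  expect_error(prediction_accuracy(m, km, km, 36, 60), "support")
})

test_that("a model equal to the generating curve has vanishing diffs", {
  set.seed(55)
  rate <- 0.05
  tt <- stats::rexp(50000, rate)
  km <- km_estimate(survival_dataset(time = tt, event = rep(1, 50000)))
  m <- psmcuts:::new_fitted_psm("exponential", NA_character_, rate, 1L,
                                0, 50000L, NULL, TRUE, "truth")
  rep <- prediction_accuracy(m, km, km, 24, 24)
  expect_lt(abs(rep$pe_diff_latest), 0.5)
  expect_lt(abs(rep$rmst_diff_latest), 0.1)
})

test_that("RMST differences convert to life-years and QALYs", {
  li <- lifeyear_impact(-1, 0.71)
  expect_equal(round(li$life_years, 2), -0.08)
  expect_equal(round(li$qalys, 2), -0.06)
  expect_equal(lifeyear_impact(0, 0.5), list(life_years = 0, qalys = 0))
  expect_equal(lifeyear_impact(12, 1), list(life_years = 1, qalys = 1))
  expect_error(lifeyear_impact(1, 1.2), "utility")
})
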