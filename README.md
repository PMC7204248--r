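# psmcuts

Parametric survival extrapolation evaluated across successive clinical
trial data cuts.

## The problem

Reimbursement and regulatory decisions for cancer treatments rest on
*lifetime* survival estimates, but trials stop following patients long
before that. Analysts therefore fit parametric survival models (PSMs) to
the observed, right-censored overall-survival data and extrapolate. For
immune-checkpoint inhibitors this is especially delicate: a fraction of
patients become long-term survivors, the Kaplan-Meier (KM) curve
plateaus, and the hazard of death rises and then falls — a pattern that
rigid constant- or monotone-hazard families cannot represent. When a
trial publishes several administrative data cuts (database locks at
increasing minimum follow-up), the later cuts can be used to score how
well models fitted to the earlier cuts actually predicted.

`psmcuts` packages that whole evaluation loop for single-arm trials:

* **Data cuts and KM** — `survival_dataset()`, `apply_data_cut()` (a
  database lock administratively censors everyone still alive at
  `lock_time - entry`), `km_estimate()`, `survival_at()`, `rmst_km()`.
* **Hazard screening** — `smoothed_hazard()` (Epanechnikov-kernel
  smoothing of the Nelson-Aalen increments, with boundary correction)
  and `classify_hazard_shape()`: a non-monotone smoothed hazard rejects
  the exponential, Weibull and Gompertz families.
* **Standard PSMs** — right-censored maximum likelihood for the
  exponential, Weibull, Gompertz, lognormal, log-logistic and
  generalized gamma families (`fit_mle()`), written against their
  natural parameterisations with deterministic restarts.
* **Royston-Parmar spline PSMs** — `fit_spline()`: a natural cubic
  spline in log time models the log cumulative hazard, log cumulative
  odds, or probit of the survivor function ("hazard", "odds", "normal"
  scales, extending Weibull / log-logistic / lognormal), with 1-3
  interior knots at percentiles of the log uncensored survival times.
* **Scoring** — `information_criteria()` computes
  `-2LL`, `AIC = -2LL + 2k`, `AICc = AIC + (2k² + 2k)/(n − k − 1)`,
  `HQC = -2LL + 2k ln(ln n)` and `BIC = -2LL + k ln(n)`;
  `rank_models()` applies the Burnham-Anderson (Δ ≤ 2) and Hilbe
  (Δ ≤ 2.5, Δ ≤ 6 at n ≤ 256) rules of thumb.
* **Prediction accuracy** — `prediction_accuracy()` compares each model
  with the KM curve of its own cut and of the latest cut, via survival
  point estimates (percentage points) and restricted mean survival time
  (months); `lifeyear_impact()` converts an RMST error into life-years
  and QALYs.
* **Synthetic trial generator** — `generator_params()`,
  `calibrate_generator()`, `simulate_trial()`: a plateau mixture
  (short-term Weibull + long-term low-rate exponential) calibrated by
  least squares to published KM summary anchors, with staggered accrual
  and database locks at fixed minimum follow-up. Everything in the
  package can be exercised without patient-level trial data.
* **Pipeline** — `run_config()`, `run_evaluation()`, `render_report()`
  orchestrate screening, fitting, scoring and accuracy for all cuts, and
  `inst/cli/psmcuts-run.R` exposes this as a command line.

## Worked example

```r
library(psmcuts)

sim <- simulate_trial(generator_params(), seed = 42)   # 4 data cuts
ds  <- sim$cuts[["12mo"]]                              # earliest cut
ds
#> Survival dataset [12mo]: n = 88, events = 57, max follow-up = 23.4 months

classify_hazard_shape(smoothed_hazard(ds, max_time = 12))
#> Hazard shape: non_monotone; rejected families: exponential, weibull, gompertz

fits <- list(lognormal     = fit_mle("lognormal", ds),
             loglogistic   = fit_mle("loglogistic", ds),
             `1-knot odds` = fit_spline("odds", 1, ds))
scores <- lapply(fits, function(f) information_criteria(f$loglik, f$k, f$n))
rank_models(scores, "AIC")[, c("label", "score", "k", "delta")]
#>         label    score k     delta
#> 1   lognormal 426.2662 2 0.0000000
#> 2 loglogistic 427.1064 2 0.8401214
#> 3 1-knot odds 428.5761 3 2.3098257

km12 <- km_estimate(ds)
km36 <- km_estimate(sim$cuts[["36mo"]])
prediction_accuracy(fits[["1-knot odds"]], km12, km36,
                    anchor_fitted = 12, anchor_latest = 36)
#> spline 1-knot odds [12mo]: PE diff -2.7 pp (fitted, 12 mo) / -6.7 pp (latest, 36 mo); RMST diff +0.0 / -0.4 months
```

The smoothed hazard of the plateauing data is non-monotone, so the three
rigid families are screened out. The lognormal has the best AIC at the
12-month cut, with the log-logistic within the Δ ≤ 2 "substantial
support" band. Fitted at 12 months of minimum follow-up, the 1-knot odds
spline matches its own cut almost exactly (−2.7 percentage points at 12
months, RMST difference 0.0 months) but under-predicts the later-revealed
36-month survival by 6.7 percentage points and the 36-month RMST by 0.4
months; `lifeyear_impact(-0.4, 0.71)` translates that shortfall into
−0.03 life-years ≈ −0.02 QALYs per patient.

The full pipeline over all cuts and the 12-model roster is one call:

```r
bundle <- run_evaluation(run_config(seed = 1))        # ~15 s
render_report(bundle, "report")                       # summary.md + plots
```

or from a shell:

```sh
Rscript inst/cli/psmcuts-run.R all --out report --seed 1
```

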