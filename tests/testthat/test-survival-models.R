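# Parametric survival families: evaluation, medians, per-cycle probabilities,
# censored MLE fitting and model selection.

test_that("survival_at matches closed forms and validates input", {
  m <- ll_bsc_pfs()
  expect_identical(survival_at(m, 0), 1)
  expect_equal(survival_at(m, 10), 1 / (1 + 0.11712 * 10^0.80840))
  expect_equal(survival_at(m, 10), 0.5703, tolerance = 1e-4)
  e <- parametric_survival("exponential", rate = 0.1)
  expect_equal(survival_at(e, 10), exp(-1))
  expect_error(survival_at(m, -1), "t must be")
  expect_error(parametric_survival("loglogistic", lambda = -1, gamma = 1),
               "must be > 0")
  expect_error(parametric_survival("weibull", shape = 1), "missing parameter")
})

test_that("all families are proper survival curves on a wide grid", {
  models <- list(
    parametric_survival("exponential", rate = 0.05),
    parametric_survival("weibull", shape = 1.3, scale = 30),
    ll_cbsc_pfs(), ll_bsc_os(),
    parametric_survival("lognormal", meanlog = 3, sdlog = 1.1),
    parametric_survival("gompertz", shape = 0.04, rate = 0.004),
    parametric_survival("gompertz", shape = -0.01, rate = 0.02)
  )
  t <- 0:600
  for (m in models) {
    s <- survival_at(m, t)
    expect_identical(s[1], 1)
    expect_true(all(diff(s) <= 1e-15))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("median_time agrees with closed forms and trial medians", {
  expect_equal(median_time(ll_bsc_pfs()), (1 / 0.11712)^(1 / 0.80840))
  expect_equal(median_time(ll_bsc_pfs()), 14.20, tolerance = 1e-3)
  med_cbsc <- median_time(ll_cbsc_pfs())
  expect_equal(med_cbsc, 54.84, tolerance = 1e-3)
  # in months (21-day cycles): close to the reported 35.9-month KM median
  expect_equal(med_cbsc * 21 / 30.4375, 37.8, tolerance = 0.01)
  expect_equal(median_time(parametric_survival("exponential", rate = log(2))),
               1.0)
  # survival_fn route agrees with the parametric closed form
  fn <- survival_fn(function(t) survival_at(ll_bsc_pfs(), t))
  expect_equal(median_time(fn), median_time(ll_bsc_pfs()), tolerance = 1e-7)
  # a defective Gompertz curve that never reaches 0.5 has no median
  expect_error(median_time(parametric_survival("gompertz", shape = -0.5,
                                               rate = 0.01)),
               "never reaches 0.5")
})

test_that("per_cycle_event_prob matches hand values and telescopes to S(t)", {
  e <- parametric_survival("exponential", rate = 0.1)
  expect_equal(per_cycle_event_prob(e, 0:9),
               rep(1 - exp(-0.1), 10))
  expect_equal(per_cycle_event_prob(ll_bsc_pfs(), 0), 1 - 1 / 1.11712,
               tolerance = 1e-7)
  models <- list(e, ll_bsc_pfs(), ll_cbsc_os(),
                 parametric_survival("weibull", shape = 0.9, scale = 25),
                 parametric_survival("lognormal", meanlog = 2.5, sdlog = 1),
                 parametric_survival("gompertz", shape = 0.03, rate = 0.01))
  for (m in models) {
    p <- per_cycle_event_prob(m, 0:49)
    expect_true(all(p >= 0 & p <= 1))
    for (t in c(1, 10, 50)) {
      expect_equal(prod(1 - p[seq_len(t)]), survival_at(m, t),
                   tolerance = 1e-12)
    }
  }
  expect_error(per_cycle_event_prob(e, -1), "non-negative")
  expect_warning(per_cycle_event_prob(e, 300), "exhausted")
})

test_that("fit_km recovers the exponential closed-form MLE", {
  set.seed(42)
  tt <- rexp(200, rate = 0.25)
  f <- fit_km(tt, rep(1, 200), "exponential")
  expect_equal(f$model$params$rate, 1 / mean(tt), tolerance = 1e-9)
  k <- 1
  expect_equal(f$aic, -2 * f$loglik + 2 * k)
  expect_equal(f$bic, -2 * f$loglik + k * log(200))
})

test_that("fit_km agrees with survreg for censored data (dual route)", {
  truth <- ll_cbsc_pfs()
  ipd <- simulate_ipd(simulation_spec(truth, 300,
                                      censor_rate = CENSOR_RATE_20,
                                      seed = 11))
  for (fam in c("exponential", "weibull", "loglogistic", "lognormal")) {
    ours <- fit_km(ipd$time, ipd$event, fam)
    dist <- if (fam == "loglogistic") "loglogistic" else fam
    sr <- survival::survreg(survival::Surv(time, event) ~ 1, data = ipd,
                            dist = dist)
    expect_equal(ours$loglik, sr$loglik[1], tolerance = 1e-5)
    mu <- unname(coef(sr)); s <- sr$scale
    ref <- switch(fam,
      exponential = list(rate = exp(-mu)),
      weibull     = list(shape = 1 / s, scale = exp(mu)),
      loglogistic = list(lambda = exp(-mu / s), gamma = 1 / s),
      lognormal   = list(meanlog = mu, sdlog = s))
    expect_equal(unlist(ours$model$params), unlist(ref), tolerance = 1e-3)
  }
})

test_that("fit_km rejects degenerate input", {
  expect_error(fit_km(1:5, rep(1, 5), "weibull"), "at least 10")
  expect_error(fit_km(1:20, rep(0, 20), "exponential"), "all observations")
  expect_error(fit_km(c(-1, 2:20), rep(1, 20), "weibull"), "times must be")
})

test_that("select_model ranks by AIC, then BIC, then family order", {
  mk <- function(fam, aic, bic) {
    structure(list(family = fam, aic = aic, bic = bic,
                   model = parametric_survival("exponential", rate = 1),
                   loglik = 0, n = 10, n_events = 10),
              class = "surv_fit")
  }
  expect_identical(select_model(list(mk("weibull", 100, 90),
                                     mk("lognormal", 90, 95)))$family,
                   "lognormal")
  expect_identical(select_model(list(mk("weibull", 90, 95),
                                     mk("lognormal", 90, 93)))$family,
                   "lognormal")
  # full tie falls back to the conventional family order
  expect_identical(select_model(list(mk("gompertz", 90, 93),
                                     mk("weibull", 90, 93)))$family,
                   "weibull")
  expect_error(select_model(list()), "empty")
  best <- select_model(list(mk("weibull", 100, 90), mk("lognormal", 90, 95)))
  expect_s3_class(attr(best, "ranking"), "data.frame")
  expect_identical(attr(best, "ranking")$family, c("lognormal", "weibull"))
})

test_that("model selection identifies the true family most of the time", {
  # exponential truth, no censoring: an exponential-equivalent fit should win
  # in >= 90% of replicates; Weibull with shape ~ 1 and Gompertz with shape
  # ~ 0 both nest the exponential and count as equivalent
  hits <- 0L
  for (s in 1:50) {
    set.seed(1000 + s)
    tt <- rexp(200, rate = 0.15)
    best <- select_model(fit_all_families(tt, rep(1, 200)))
    ok <- switch(best$family,
                 exponential = TRUE,
                 weibull = abs(best$model$params$shape - 1) < 0.15,
                 gompertz = abs(best$model$params$shape) < 0.05,
                 FALSE)
    hits <- hits + ok
  }
  expect_gte(hits / 50, 0.9)

  # log-logistic truth at n = 500 with ~20% censoring: selected >= 80%
  truth <- parametric_survival("loglogistic", lambda = 0.0346, gamma = 0.84)
  sel <- vapply(1:50, function(s) {
    ipd <- simulate_ipd(simulation_spec(truth, 500,
                                        censor_rate = CENSOR_RATE_20,
                                        seed = s))
    select_model(fit_all_families(ipd$time, ipd$event))$family
  }, character(1))
  expect_gte(mean(sel == "loglogistic"), 0.8)
})

test_that("ph_adjust applies S^hr", {
  m <- ll_bsc_pfs()
  adj <- ph_adjust(m, 0.44)
  tstar <- median_time(m)
  expect_equal(survival_at(adj, tstar), 0.5^0.44, tolerance = 1e-9)
  expect_equal(survival_at(adj, tstar), 0.7371, tolerance = 1e-4)
  expect_equal(survival_at(ph_adjust(m, 1), c(0, 5, 20)),
               survival_at(m, c(0, 5, 20)))
  expect_equal(survival_at(ph_adjust(m, 2), tstar), 0.25, tolerance = 1e-9)
  expect_error(ph_adjust(m, 0), "positive")
})
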