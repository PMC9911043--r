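# Shared fixtures, built once per test run.

fixture_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- baseline_fixture()
    cfg
  }
})

# the four published log-logistic curves (time in 21-day cycles)
ll_bsc_pfs <- function() parametric_survival("loglogistic",
                                             lambda = 0.11712, gamma = 0.80840)
ll_cbsc_pfs <- function() parametric_survival("loglogistic",
                                              lambda = 0.034595,
                                              gamma = 0.840056)
ll_bsc_os <- function() parametric_survival("loglogistic",
                                            lambda = 0.0051219,
                                            gamma = 1.3690167)
ll_cbsc_os <- function() parametric_survival("loglogistic",
                                             lambda = 0.006220,
                                             gamma = 1.070002)

# exponential censoring rate that gives ~20% censoring for
# loglogistic(0.0346, 0.84) pseudo-IPD (calibrated once)
CENSOR_RATE_20 <- 0.0016

# quiet wrapper: run_cohort messages when extrapolated curves cross
quiet_base_case <- function(cfg, ...) {
  suppressMessages(run_base_case(cfg, ...))
}
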