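Package: ceamaint
Title: Cost-Utility Analysis of Maintenance Therapy via Partitioned-Survival Cohort Models
Version: 0.1.0
Authors@R:
    person("Model", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A decision-analytic pipeline for trial-based cost-utility analysis
    of maintenance therapy versus supportive care in metastatic nasopharyngeal
    carcinoma. Fits and extrapolates parametric survival curves (exponential,
    Weibull, log-logistic, lognormal, Gompertz) from pseudo individual patient
    data, runs a four-state partitioned-survival cohort model with background
    mortality, half-cycle correction and discounting, accrues discounted costs,
    QALYs and life-years, and computes incremental cost-utility measures (ICUR,
    ICER, INMB, INHB). Includes one-way (tornado) and probabilistic (Monte
    Carlo) sensitivity analyses with cost-effectiveness acceptability curves,
    hazard-ratio-based subgroup analysis, a synthetic-data generator for
    pseudo-IPD and life tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
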