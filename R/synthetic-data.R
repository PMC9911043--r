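# Synthetic inputs: pseudo-IPD with known ground truth, a Gompertz-Makeham
# life table, and the complete baseline model configuration.

#' Specification for simulating pseudo-IPD
#'
#' @param model True [parametric_survival()] model (time in cycles).
#' @param n Number of subjects, `>= 1`.
#' @param admin_censor Administrative censoring time in cycles (default `Inf`).
#' @param censor_rate Rate of an independent exponential censoring process per
#'   cycle (default 0 = none).
#' @param seed Integer seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(model, n, admin_censor = Inf, censor_rate = 0,
                            seed = 1) {
  stopifnot(inherits(model, "parametric_survival"), n >= 1,
            admin_censor >= 0, censor_rate >= 0)
  structure(list(model = model, n = as.integer(n),
                 admin_censor = admin_censor, censor_rate = censor_rate,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate right-censored pseudo-IPD
#'
#' Event times are drawn by inverse-CDF sampling from the true model
#' (uniform `u` mapped through the inverse survival function, e.g. for the
#' log-logistic \eqn{t = ((1-u)/(\lambda u))^{1/\gamma}}); each subject is
#' censored at the minimum of the administrative cutoff and an independent
#' exponential censoring time.
#'
#' @param spec A [simulation_spec()].
#' @return Data frame `time` (cycles), `event` (1 = event, 0 = censored).
#' @export
simulate_ipd <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  u <- stats::runif(spec$n)
  t_event <- surv_inverse(spec$model, u)
  t_cens <- rep(spec$admin_censor, spec$n)
  if (spec$censor_rate > 0) {
    t_cens <- pmin(t_cens, stats::rexp(spec$n, spec$censor_rate))
  }
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Kaplan-Meier estimate from pseudo-IPD
#'
#' Product-limit estimator (via [survival::survfit()]), standing in for
#' digitized published curves.
#'
#' @param ipd Data frame with columns `time`, `event`.
#' @return Data frame `time, surv, n_risk` including the `(0, 1)` origin.
#' @export
km_estimate <- function(ipd) {
  stopifnot(all(c("time", "event") %in% names(ipd)))
  if (sum(ipd$event) < 1) {
    stop("km_estimate: no events in the data", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  data.frame(time = c(0, fit$time), surv = c(1, fit$surv),
             n_risk = c(nrow(ipd), fit$n.risk))
}

#' Kaplan-Meier survival at given times
#'
#' Step-function lookup of a [km_estimate()] curve.
#' @param km Data frame from [km_estimate()].
#' @param t Times in cycles.
#' @return Survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  stats::approx(km$time, km$surv, xout = t, method = "constant",
                yleft = 1, rule = 2)$y
}

#' Synthetic Gompertz-Makeham life table
#'
#' Annual death probability \eqn{q_x = 1 - \exp(-(a + b e^{c\,x}))}, with
#' `qx` forced to 1 at the maximum age. The defaults approximate modern
#' East-Asian adult mortality; this is a synthetic stand-in, not a published
#' national table.
#'
#' @param makeham_a Age-independent hazard component (default 5e-4).
#' @param gompertz_b Gompertz level (default 3e-5).
#' @param gompertz_c Gompertz slope per year (default 0.09).
#' @param max_age Maximum (absorbing) age, `>= 100` (default 100).
#' @param min_age Minimum age (default 0).
#' @return A [life_table()].
#' @export
synthetic_life_table <- function(makeham_a = 5e-4, gompertz_b = 3e-5,
                                 gompertz_c = 0.09, max_age = 100,
                                 min_age = 0) {
  stopifnot(makeham_a >= 0, gompertz_b >= 0, max_age >= 100)
  age <- min_age:max_age
  qx <- 1 - exp(-(makeham_a + gompertz_b * exp(gompertz_c * age)))
  if (any(qx < 0 | qx > 1)) {
    stop("synthetic_life_table: parameters give qx outside [0, 1]",
         call. = FALSE)
  }
  qx[length(qx)] <- 1
  life_table(age, qx)
}

# gamma PSA entry; published rates are rounded to 2 d.p., so whenever the
# implied mean misses the baseline by > 1% the rate is re-derived as
# shape / baseline (preserving the shape, hence the coefficient of variation)
fixture_gamma <- function(path, shape, printed_rate, baseline) {
  rate <- printed_rate
  adjusted <- FALSE
  if (abs(shape / printed_rate - baseline) > 0.01 * baseline) {
    rate <- shape / baseline
    adjusted <- TRUE
  }
  list(path = path, kind = "gamma", shape = shape, rate = rate,
       printed_rate = printed_rate, adjusted = adjusted)
}

fixture_beta <- function(path, alpha, beta, min = NULL, max = NULL) {
  out <- list(path = path, kind = "beta", alpha = alpha, beta = beta)
  if (!is.null(min)) out$min <- min
  if (!is.null(max)) out$max <- max
  out
}

#' Baseline model configuration
#'
#' Builds the complete two-strategy configuration: published baseline values,
#' one-way ranges and sampling distributions for every model parameter
#' (survival parameters, therapy proportions, adverse-event incidences, unit
#' costs, utilities, discount rate, willingness-to-pay $36,007/QALY), plus the
#' implementation's own defaults under `assumptions` (dosage-unit sizes,
#' recurrence intervals, start age, maintenance cap) and a synthetic life
#' table and subgroup grid, both flagged as such.
#'
#' @param life_table_fixture A [life_table()] (default
#'   [synthetic_life_table()]).
#' @return A validated configuration list.
#' @export
baseline_fixture <- function(life_table_fixture = synthetic_life_table()) {
  cfg <- list(
    settings = list(
      start_age = 45, discount_rate = 0.03, horizon = 1000,
      half_cycle_correction = TRUE, cycle_days = 21, wtp = 36007
    ),
    patient = list(weight = 65, bsa = 1.72),
    survival = list(
      cbsc = list(
        os = list(family = "loglogistic", lambda = 0.006220,
                  gamma = 1.070002),
        pfs = list(family = "loglogistic", lambda = 0.034595,
                   gamma = 0.840056)
      ),
      bsc = list(
        os = list(family = "loglogistic", lambda = 0.0051219,
                  gamma = 1.3690167),
        pfs = list(family = "loglogistic", lambda = 0.11712,
                   gamma = 0.80840)
      )
    ),
    utility = list(pfs = 0.760, pd = 0.350, death = 0, ae_disutility = 0),
    costs = list(
      drug = list(
        capecitabine = 1.91, paclitaxel = 27.94, cisplatin = 3.00,
        bisphosphonates = 250.47, docetaxel = 75.56, gemcitabine = 26.05,
        irinotecan = 159.20, camrelizumab = 458.93, toripalimab = 142.01,
        nivolumab = 1451.41, pembrolizumab = 2808.46
      ),
      radiotherapy = 3690.64,
      bsc_per_cycle = 274.00,
      imaging = 176.49,
      lab = 82.59,
      ae = list(
        anemia = 6434.00, neutropenia = 466.00, thrombocytopenia = 3551.70,
        hand_foot_syndrome = 773.64, nausea_vomiting = 44.30,
        mucositis = 3719.00, fatigue = 107.01
      ),
      shared_one_off = 0
    ),
    strategies = list(
      cbsc = list(
        concomitant = list(radiotherapy = 0.528, bisphosphonates = 0.512),
        subsequent = list(chemotherapy = 0.608, radiotherapy = 0.087,
                          immunotherapy = 0.087),
        ae_incidence = list(
          anemia = 0.120, neutropenia = 0.020, thrombocytopenia = 0.020,
          hand_foot_syndrome = 0.100, nausea_vomiting = 0.060,
          mucositis = 0.040, fatigue = 0.040
        ),
        maintenance = list(
          drug = "capecitabine", dose = 1000, basis = "bsa",
          admins_per_cycle = 28, unit_size = 500, rounding = "per_admin",
          max_cycles = 35
        )
      ),
      bsc = list(
        concomitant = list(radiotherapy = 0.476, bisphosphonates = 0.488),
        subsequent = list(chemotherapy = 0.467, radiotherapy = 0.054,
                          immunotherapy = 0.162),
        ae_incidence = list(
          anemia = 0.021, neutropenia = 0, thrombocytopenia = 0,
          hand_foot_syndrome = 0, nausea_vomiting = 0, mucositis = 0,
          fatigue = 0
        ),
        maintenance = NULL
      )
    ),
    # implementation defaults, not published values
    assumptions = list(
      imaging_interval_cycles = 3,
      pd_subsequent_cap_cycles = 6,
      ae_cost_cycle = 1,
      bisphosphonate_units_per_cycle = 1,
      subsequent = list(
        chemotherapy = list(
          gemcitabine = list(drug = "gemcitabine", dose = 1000,
                             basis = "bsa", admins_per_cycle = 2,
                             unit_size = 200, rounding = "per_cycle"),
          cisplatin = list(drug = "cisplatin", dose = 75, basis = "bsa",
                           admins_per_cycle = 1, unit_size = 10,
                           rounding = "per_cycle")
        ),
        immunotherapy = list(
          camrelizumab = list(drug = "camrelizumab", dose = 200,
                              basis = "flat", admins_per_cycle = 1,
                              unit_size = 200, rounding = "per_cycle")
        )
      )
    ),
    life_table = list(age = life_table_fixture$age,
                      qx = life_table_fixture$qx),
    # trial-level PFS HR plus a synthetic placeholder grid (subgroup-specific
    # HRs are not published numerically)
    subgroups = list(
      list(name = "overall (trial-level HR)", hr = 0.44, hr_low = 0.26,
           hr_high = 0.74),
      list(name = "synthetic subgroup HR 0.30", hr = 0.30, hr_low = 0.20,
           hr_high = 0.45),
      list(name = "synthetic subgroup HR 0.60", hr = 0.60, hr_low = 0.40,
           hr_high = 0.90),
      list(name = "synthetic subgroup HR 0.90", hr = 0.90, hr_low = 0.60,
           hr_high = 1.35)
    )
  )

  cfg$psa <- c(
    list(
      fixture_gamma("costs.drug.capecitabine", 96.04, 50.28, 1.91),
      fixture_gamma("costs.drug.paclitaxel", 96.04, 3.44, 27.94),
      fixture_gamma("costs.drug.cisplatin", 96.04, 32.01, 3.00),
      fixture_gamma("costs.drug.bisphosphonates", 96.04, 0.383, 250.47),
      fixture_gamma("costs.drug.docetaxel", 96.04, 1.27, 75.56),
      fixture_gamma("costs.drug.gemcitabine", 96.04, 3.69, 26.05),
      fixture_gamma("costs.drug.irinotecan", 96.04, 0.60, 159.20),
      fixture_gamma("costs.drug.camrelizumab", 96.04, 0.21, 458.93),
      fixture_gamma("costs.drug.toripalimab", 96.04, 0.68, 142.01),
      fixture_gamma("costs.drug.nivolumab", 96.04, 0.07, 1451.41),
      fixture_gamma("costs.drug.pembrolizumab", 96.04, 0.03, 2808.46),
      fixture_gamma("costs.radiotherapy", 96.04, 0.03, 3690.64),
      fixture_gamma("patient.weight", 15.37, 0.24, 65),
      fixture_gamma("patient.bsa", 96.04, 55.84, 1.72),
      fixture_gamma("costs.bsc_per_cycle", 96.04, 0.35, 274.00),
      fixture_gamma("costs.imaging", 96.03, 0.54, 176.49),
      fixture_gamma("costs.lab", 96.02, 1.16, 82.59),
      fixture_gamma("costs.ae.anemia", 96.04, 0.01, 6434.00),
      fixture_gamma("costs.ae.neutropenia", 96.04, 0.21, 466.00),
      fixture_gamma("costs.ae.thrombocytopenia", 96.04, 0.03, 3551.70),
      fixture_gamma("costs.ae.hand_foot_syndrome", 86.37, 0.12, 773.64),
      fixture_gamma("costs.ae.nausea_vomiting", 96.04, 2.17, 44.30),
      fixture_gamma("costs.ae.mucositis", 96.04, 0.03, 3719.00),
      fixture_gamma("costs.ae.fatigue", 96.04, 0.98, 107.01)
    ),
    list(
      fixture_beta("strategies.cbsc.concomitant.radiotherapy", 0.528, 0.472),
      fixture_beta("strategies.cbsc.concomitant.bisphosphonates",
                   0.512, 0.488),
      fixture_beta("strategies.bsc.concomitant.radiotherapy", 0.476, 0.524),
      fixture_beta("strategies.bsc.concomitant.bisphosphonates",
                   0.488, 0.512),
      fixture_beta("strategies.cbsc.subsequent.chemotherapy", 0.608, 0.392),
      fixture_beta("strategies.cbsc.subsequent.radiotherapy", 0.087, 0.913),
      fixture_beta("strategies.cbsc.subsequent.immunotherapy", 0.087, 0.913),
      fixture_beta("strategies.bsc.subsequent.chemotherapy", 0.467, 0.533),
      fixture_beta("strategies.bsc.subsequent.radiotherapy", 0.054, 0.946),
      fixture_beta("strategies.bsc.subsequent.immunotherapy", 0.162, 0.838),
      fixture_beta("strategies.cbsc.ae_incidence.anemia", 6, 44),
      fixture_beta("strategies.cbsc.ae_incidence.neutropenia", 1, 49),
      fixture_beta("strategies.cbsc.ae_incidence.thrombocytopenia", 1, 49),
      fixture_beta("strategies.cbsc.ae_incidence.hand_foot_syndrome", 5, 45),
      fixture_beta("strategies.cbsc.ae_incidence.nausea_vomiting", 3, 47),
      fixture_beta("strategies.cbsc.ae_incidence.mucositis", 2, 48),
      fixture_beta("strategies.cbsc.ae_incidence.fatigue", 2, 48),
      fixture_beta("strategies.bsc.ae_incidence.anemia", 1, 47),
      fixture_beta("utility.pfs", 0.76, 0.24),
      fixture_beta("utility.pd", 0.35, 0.65),
      # published beta support is (0,1); clamp to the admissible range
      fixture_beta("settings.discount_rate", 0.03, 0.97, min = 0, max = 0.08)
    )
  )

  # one-way ranges: +/-20% everywhere except the discount rate's 0-0.08
  cfg$owsa <- lapply(cfg$psa, function(e) {
    base <- get_config_value(cfg, e$path)
    if (e$path == "settings.discount_rate") {
      list(path = e$path, low = 0, high = 0.08)
    } else {
      r <- owsa_range(base)
      list(path = e$path, low = unname(r["low"]), high = unname(r["high"]))
    }
  })

  validate_config(cfg)
}

#' Write pseudo-IPD to CSV (`time_cycles,event`)
#'
#' @param ipd Data frame `time, event`.
#' @param path Output path.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(data.frame(time_cycles = ipd$time, event = ipd$event),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read pseudo-IPD from CSV (`time_cycles,event`)
#'
#' @param path CSV path.
#' @return Data frame `time, event`.
#' @export
read_ipd <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_cycles", "event") %in% names(d))) {
    stop("read_ipd: CSV must have columns time_cycles,event", call. = FALSE)
  }
  data.frame(time = d$time_cycles, event = as.integer(d$event))
}
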