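# Cost/QALY/LY accrual per strategy and incremental cost-utility measures.

#' Drug regimen specification
#'
#' @param drug Drug name; its unit cost is looked up in `costs.drug` of the
#'   model configuration.
#' @param dose Dose per administration, per m2 (basis `"bsa"`), per kg
#'   (`"weight"`) or absolute (`"flat"`).
#' @param basis Dosing basis: `"bsa"`, `"weight"` or `"flat"`.
#' @param admins_per_cycle Administrations per 21-day cycle (e.g. twice daily
#'   on days 1-14 = 28).
#' @param unit_size Size of the smallest dispensed unit (mg per tablet/vial).
#' @param rounding `"per_admin"` (tablets: round up each administration) or
#'   `"per_cycle"` (vials: round up the cycle total).
#' @return A `drug_regimen` list.
#' @export
drug_regimen <- function(drug, dose, basis = c("bsa", "weight", "flat"),
                         admins_per_cycle, unit_size,
                         rounding = c("per_admin", "per_cycle")) {
  basis <- match.arg(basis)
  rounding <- match.arg(rounding)
  stopifnot(dose >= 0, admins_per_cycle >= 0, unit_size > 0)
  structure(list(drug = drug, dose = dose, basis = basis,
                 admins_per_cycle = admins_per_cycle, unit_size = unit_size,
                 rounding = rounding),
            class = "drug_regimen")
}

#' Patient characteristics used for dosing
#'
#' @param weight Body weight in kg (baseline 65).
#' @param bsa Body surface area in m2 (baseline 1.72).
#' @return A `patient` list.
#' @export
patient <- function(weight = 65, bsa = 1.72) {
  stopifnot(weight > 0, bsa > 0)
  structure(list(weight = weight, bsa = bsa), class = "patient")
}

#' Total drug amount administered per cycle
#'
#' @param regimen A [drug_regimen()].
#' @param patient A [patient()].
#' @return Amount per cycle (mg): dose x dosing multiplier x administrations.
#' @export
regimen_cycle_amount <- function(regimen, patient) {
  mult <- switch(regimen$basis,
                 bsa = patient$bsa, weight = patient$weight, flat = 1)
  regimen$dose * mult * regimen$admins_per_cycle
}

#' Dosage units dispensed per cycle
#'
#' Rounds the administered amount up to whole dispensed units: per
#' administration for tablets, per cycle for vials.
#'
#' @inheritParams regimen_cycle_amount
#' @return Number of dosage units per cycle.
#' @export
regimen_cycle_quantity <- function(regimen, patient) {
  if (regimen$dose == 0 || regimen$admins_per_cycle == 0) return(0)
  mult <- switch(regimen$basis,
                 bsa = patient$bsa, weight = patient$weight, flat = 1)
  per_admin <- regimen$dose * mult
  if (regimen$rounding == "per_admin") {
    ceiling(per_admin / regimen$unit_size) * regimen$admins_per_cycle
  } else {
    ceiling(per_admin * regimen$admins_per_cycle / regimen$unit_size)
  }
}

#' Drug cost of a regimen per cycle
#'
#' @inheritParams regimen_cycle_amount
#' @param unit_costs Named list/vector of cost per dosage unit (US$) by drug.
#' @return Cost per cycle (US$).
#' @export
regimen_cycle_cost <- function(regimen, patient, unit_costs) {
  uc <- unit_costs[[regimen$drug]]
  if (is.null(uc)) {
    stop("regimen_cycle_cost: no unit cost configured for drug '",
         regimen$drug, "'", call. = FALSE)
  }
  regimen_cycle_quantity(regimen, patient) * uc
}

#' Expected one-off adverse-event management cost
#'
#' Sum over adverse events of incidence x management cost, the expected
#' per-patient cost applied once at the start of treatment.
#'
#' @param incidences Named list/vector of grade 3-4 incidence per event type.
#' @param costs Named list/vector of management cost (US$) per event type.
#' @return Expected cost (US$).
#' @export
expected_ae_cost <- function(incidences, costs) {
  inc <- unlist(incidences)
  cst <- unlist(costs)
  if (any(inc < 0 | inc > 1)) {
    stop("expected_ae_cost: incidences must lie in [0, 1]", call. = FALSE)
  }
  active <- names(inc)[inc > 0]
  missing <- setdiff(active, names(cst))
  if (length(missing)) {
    stop("expected_ae_cost: no cost configured for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!length(active)) return(0)
  sum(inc[active] * cst[active])
}

#' Probability of experiencing at least one adverse event
#'
#' `1 - prod(1 - incidence_i)`; used to split the progression-free compartment
#' into with/without adverse-event sub-states.
#'
#' @param incidences Named list/vector of incidences in `[0, 1]`.
#' @return Probability in `[0, 1]`.
#' @export
any_ae_prob <- function(incidences) {
  inc <- unlist(incidences)
  if (!length(inc)) return(0)
  1 - prod(1 - inc)
}

# per-cycle cost of subsequent (post-progression) therapy: proportion-weighted
# mean over the chemotherapy / radiotherapy / immunotherapy options, with the
# radiotherapy course amortized over the PD cost cap
subsequent_cycle_cost <- function(config, arm) {
  props <- config$strategies[[arm]]$subsequent
  pat <- do.call(patient, config$patient)
  cap <- config$assumptions$pd_subsequent_cap_cycles
  regimen_block_cost <- function(block) {
    sum(vapply(block, function(r) {
      regimen_cycle_cost(do.call(drug_regimen, r), pat, config$costs$drug)
    }, numeric(1)))
  }
  chemo <- regimen_block_cost(config$assumptions$subsequent$chemotherapy)
  immuno <- regimen_block_cost(config$assumptions$subsequent$immunotherapy)
  radio <- config$costs$radiotherapy / cap
  props$chemotherapy * chemo + props$radiotherapy * radio +
    props$immunotherapy * immuno
}

# new entrants into the progressed-disease state per cycle, attributing cohort
# deaths preferentially to the PD compartment (disease deaths dominate here)
pd_entrants <- function(trace) {
  pd <- trace$pd
  death <- trace$death
  n <- length(pd)
  if (n < 2) return(numeric(0))
  d_death <- diff(death)
  pd_deaths <- pmin(d_death, pd[-n])
  pmax(pd[-1] - (pd[-n] - pd_deaths), 0)
}

#' Run one strategy through the cohort model and accrue economics
#'
#' Builds the strategy's state trace and accrues discounted costs, QALYs and
#' life-years. Cost components: maintenance drug cost in the progression-free
#' states up to the maintenance cap; best supportive care, laboratory tests,
#' amortized imaging and proportion-weighted bisphosphonates in all alive
#' states; one-off concomitant radiotherapy (proportion-weighted) and expected
#' adverse-event management costs at model entry; subsequent-therapy costs
#' charged per new progressed-disease entrant for a capped number of cycles.
#'
#' @param config A validated model configuration (see [baseline_fixture()]).
#' @param arm Strategy name, `"cbsc"` or `"bsc"`.
#' @param pfs Optional survival-model override for the arm's PFS curve (used
#'   by the hazard-ratio subgroup machinery).
#' @return A `strategy_result`: list with `name`, `cost`, `qaly`, `ly`,
#'   `cost_pfs`, `cost_pd`, `qaly_pfs`, `qaly_pd` and the `trace`.
#' @export
run_strategy <- function(config, arm, pfs = NULL) {
  strat <- config$strategies[[arm]]
  if (is.null(strat)) stop("run_strategy: unknown arm '", arm, "'",
                           call. = FALSE)
  settings <- do.call(engine_settings,
                      config$settings[setdiff(names(config$settings), "wtp")])
  tbl <- if (!is.null(config$life_table)) {
    life_table(config$life_table$age, config$life_table$qx)
  }
  os <- config_surv_model(config$survival[[arm]]$os)
  if (is.null(pfs)) pfs <- config_surv_model(config$survival[[arm]]$pfs)
  ae_split <- any_ae_prob(strat$ae_incidence)

  trace <- run_cohort(pfs, os, tbl, settings, ae_split)
  n <- nrow(trace)
  ypc <- settings$cycle_days / DAYS_PER_YEAR
  pat <- do.call(patient, config$patient)

  u <- config$utility
  qaly_vals <- c(pfs_no_ae = u$pfs, pfs_ae = u$pfs - u$ae_disutility,
                 pd = u$pd, death = u$death) * ypc
  ly_vals <- c(pfs_no_ae = 1, pfs_ae = 1, pd = 1, death = 0) * ypc

  # recurring per-cycle costs
  alive_cost <- config$costs$bsc_per_cycle + config$costs$lab +
    config$costs$imaging / config$assumptions$imaging_interval_cycles +
    strat$concomitant$bisphosphonates * config$costs$drug$bisphosphonates *
      config$assumptions$bisphosphonate_units_per_cycle
  cost_mat <- matrix(0, n, 4, dimnames = list(NULL, STATE_NAMES))
  cost_mat[, c("pfs_no_ae", "pfs_ae", "pd")] <- alive_cost
  if (!is.null(strat$maintenance)) {
    m <- strat$maintenance
    reg <- drug_regimen(m$drug, m$dose, m$basis, m$admins_per_cycle,
                        m$unit_size, m$rounding)
    drug_cost <- regimen_cycle_cost(reg, pat, config$costs$drug)
    on <- trace$cycle < m$max_cycles
    cost_mat[on, "pfs_no_ae"] <- cost_mat[on, "pfs_no_ae"] + drug_cost
    cost_mat[on, "pfs_ae"] <- cost_mat[on, "pfs_ae"] + drug_cost
  }

  qaly_mat <- matrix(rep(qaly_vals, each = n), n,
                     dimnames = list(NULL, STATE_NAMES))
  mask_pfs <- c(1, 1, 0, 0)
  mask_pd <- c(0, 0, 1, 0)

  acc <- function(mat, mask) {
    accrue(trace, sweep(mat, 2, mask, `*`), settings)
  }
  cost_pfs_rec <- acc(cost_mat, mask_pfs)
  cost_pd_rec <- acc(cost_mat, mask_pd)
  qaly_pfs <- acc(qaly_mat, mask_pfs)
  qaly_pd <- acc(qaly_mat, mask_pd)
  ly <- accrue(trace, ly_vals, settings)

  # one-off costs
  df1 <- discount_factor(config$assumptions$ae_cost_cycle,
                         settings$discount_rate, settings$cycle_days)
  ae_cost <- expected_ae_cost(strat$ae_incidence, config$costs$ae) * df1
  radio_cost <- strat$concomitant$radiotherapy * config$costs$radiotherapy
  shared <- config$costs$shared_one_off
  # subsequent therapy: lump per new PD entrant, discounted at entry cycle
  sub_pc <- subsequent_cycle_cost(config, arm)
  ent <- pd_entrants(trace)
  cap <- config$assumptions$pd_subsequent_cap_cycles
  sub_cost <- sum(ent * trace$discount_factor[-1]) * cap * sub_pc
  # include entrants already progressed at model entry, if any
  sub_cost <- sub_cost + trace$pd[1] * cap * sub_pc

  cost_pfs <- cost_pfs_rec + ae_cost + radio_cost + shared
  cost_pd <- cost_pd_rec + sub_cost

  structure(list(
    name = arm,
    cost = cost_pfs + cost_pd,
    qaly = qaly_pfs + qaly_pd,
    ly = ly,
    cost_pfs = cost_pfs, cost_pd = cost_pd,
    qaly_pfs = qaly_pfs, qaly_pd = qaly_pd,
    trace = trace
  ), class = "strategy_result")
}

# build a survival model from its config block (family + parameters)
config_surv_model <- function(block) {
  fam <- block$family
  pars <- block[setdiff(names(block), "family")]
  do.call(parametric_survival, c(list(fam), pars))
}

#' Incremental cost-utility measures
#'
#' Computes the four indices comparing a treated strategy (1) with a control
#' (0): the incremental cost-utility ratio \eqn{ICUR = \Delta C / \Delta U},
#' the incremental cost-effectiveness ratio \eqn{ICER = \Delta C / \Delta E}
#' (per life-year), the incremental net monetary benefit
#' \eqn{INMB = \Delta U \cdot WTP - \Delta C} and the incremental net health
#' benefit \eqn{INHB = \Delta U - \Delta C / WTP}.
#'
#' Either supply two [run_strategy()] results, or feed increments directly via
#' `delta_cost` / `delta_qaly` / `delta_ly`.
#'
#' @param treated,control `strategy_result` objects (or `NULL` when passing
#'   increments).
#' @param wtp Willingness-to-pay threshold in $/QALY, `> 0` (baseline 36007).
#' @param delta_cost,delta_qaly,delta_ly Increments (treated minus control).
#' @return A `comparison_result`: list with `delta_cost`, `delta_qaly`,
#'   `delta_ly`, `icur`, `icer`, `inmb`, `inhb`, `wtp`, `dominant`,
#'   `dominated`. Ratios are `NA` when their denominator is zero.
#' @export
incremental_measures <- function(treated = NULL, control = NULL, wtp = 36007,
                                 delta_cost = NULL, delta_qaly = NULL,
                                 delta_ly = NULL) {
  if (!is.numeric(wtp) || wtp <= 0) {
    stop("incremental_measures: wtp must be > 0", call. = FALSE)
  }
  if (!is.null(treated)) {
    stopifnot(inherits(treated, "strategy_result"),
              inherits(control, "strategy_result"))
    delta_cost <- treated$cost - control$cost
    delta_qaly <- treated$qaly - control$qaly
    delta_ly <- treated$ly - control$ly
  }
  if (is.null(delta_cost) || is.null(delta_qaly)) {
    stop("incremental_measures: supply strategy results or increments",
         call. = FALSE)
  }
  if (is.null(delta_ly)) delta_ly <- NA_real_
  icur <- if (delta_qaly != 0) delta_cost / delta_qaly else NA_real_
  icer <- if (!is.na(delta_ly) && delta_ly != 0) delta_cost / delta_ly
          else NA_real_
  structure(list(
    delta_cost = delta_cost, delta_qaly = delta_qaly, delta_ly = delta_ly,
    icur = icur, icer = icer,
    inmb = delta_qaly * wtp - delta_cost,
    inhb = delta_qaly - delta_cost / wtp,
    wtp = wtp,
    dominant = delta_cost < 0 && delta_qaly > 0,
    dominated = delta_cost > 0 && delta_qaly < 0
  ), class = "comparison_result")
}

#' Run the base-case two-strategy comparison
#'
#' @param config A validated model configuration.
#' @param wtp Willingness-to-pay threshold; defaults to `config$settings$wtp`.
#' @return List with elements `cbsc`, `bsc` (strategy results) and
#'   `comparison` (a `comparison_result`).
#' @export
run_base_case <- function(config, wtp = NULL) {
  if (is.null(wtp)) wtp <- config$settings$wtp
  arms <- names(config$strategies)
  stopifnot(length(arms) == 2)
  treated <- run_strategy(config, arms[1])
  control <- run_strategy(config, arms[2])
  res <- list(treated, control,
              comparison = incremental_measures(treated, control, wtp))
  names(res)[1:2] <- arms
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    paste0("<comparison_result>\n",
           "  delta cost  : $%.0f\n  delta QALYs : %.3f\n",
           "  delta LYs   : %.3f\n  ICUR        : $%.0f/QALY\n",
           "  ICER        : $%.0f/LY\n  INMB        : $%.0f\n",
           "  INHB        : %.3f QALYs (WTP $%.0f/QALY)\n"),
    x$delta_cost, x$delta_qaly, x$delta_ly, x$icur, x$icer, x$inmb,
    x$inhb, x$wtp))
  invisible(x)
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf(
    "<strategy_result> %s: cost $%.0f, %.3f QALYs, %.3f LYs\n",
    x$name, x$cost, x$qaly, x$ly))
  invisible(x)
}
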