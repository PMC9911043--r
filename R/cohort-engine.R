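# Four-state partitioned-survival cohort engine with background mortality,
# discounting and half-cycle (trapezoidal) correction.

DAYS_PER_YEAR <- 365.25

STATE_NAMES <- c("pfs_no_ae", "pfs_ae", "pd", "death")

#' Engine settings
#'
#' @param start_age Cohort age at model entry, years (default 45).
#' @param discount_rate Annual discount rate for costs and effects, in
#'   `[0, 0.08]` (default 0.03).
#' @param horizon Maximum number of cycles (default 1000; "lifetime" in
#'   practice, since the run also stops when the cohort is dead or the life
#'   table is exhausted).
#' @param half_cycle_correction Apply trapezoidal half-cycle correction when
#'   accruing (default `TRUE`).
#' @param cycle_days Cycle length in days (default 21; one treatment cycle).
#' @return An `engine_settings` list.
#' @export
engine_settings <- function(start_age = 45, discount_rate = 0.03,
                            horizon = 1000, half_cycle_correction = TRUE,
                            cycle_days = 21) {
  stopifnot(start_age > 0, horizon >= 1, cycle_days > 0)
  if (discount_rate < 0 || discount_rate > 0.08) {
    stop("engine_settings: discount_rate must lie in [0, 0.08]", call. = FALSE)
  }
  structure(list(start_age = start_age, discount_rate = discount_rate,
                 horizon = as.integer(horizon),
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 cycle_days = cycle_days),
            class = "engine_settings")
}

#' Construct a life table
#'
#' @param age Integer ages in whole years, contiguous.
#' @param qx Annual all-cause death probability at each age; the final age
#'   must have `qx = 1` (absorbing end of the table).
#' @return A `life_table` data frame with columns `age`, `qx`.
#' @export
life_table <- function(age, qx) {
  stopifnot(length(age) == length(qx))
  age <- as.integer(age)
  if (any(diff(age) != 1L)) {
    stop("life_table: ages must be contiguous whole years", call. = FALSE)
  }
  if (any(qx < 0 | qx > 1)) {
    stop("life_table: qx must lie in [0, 1]", call. = FALSE)
  }
  if (qx[length(qx)] != 1) {
    stop("life_table: qx at the maximum age must equal 1", call. = FALSE)
  }
  structure(data.frame(age = age, qx = qx),
            class = c("life_table", "data.frame"))
}

#' Read a life table from CSV
#'
#' Expects header `age,qx`.
#' @param path CSV path.
#' @return A [life_table()].
#' @export
read_life_table <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(d))) {
    stop("read_life_table: CSV must have columns age,qx", call. = FALSE)
  }
  life_table(d$age, d$qx)
}

#' Per-cycle other-cause death probability
#'
#' Converts the annual probability `qx` at the (floored) current age to the
#' cycle scale via \eqn{1 - (1 - q_x)^{d/365.25}} with `d` the cycle length in
#' days. Ages beyond the table are clamped to its maximum (where `qx = 1`).
#'
#' @param table A [life_table()], or `NULL` for no background mortality.
#' @param current_age Age in years (vectorized).
#' @param cycle_days Cycle length in days (default 21).
#' @return Per-cycle death probabilities.
#' @export
other_cause_prob <- function(table, current_age, cycle_days = 21) {
  if (is.null(table)) return(rep(0, length(current_age)))
  if (any(current_age < min(table$age))) {
    stop("other_cause_prob: age below life-table minimum", call. = FALSE)
  }
  idx <- pmin(floor(current_age), max(table$age)) - min(table$age) + 1L
  qx <- table$qx[idx]
  1 - (1 - qx)^(cycle_days / DAYS_PER_YEAR)
}

#' Combine two independent sources of mortality
#'
#' @param p_disease,p_other Per-cycle probabilities in `[0, 1]`.
#' @return \eqn{1 - (1-p_d)(1-p_o)}.
#' @export
combine_mortality <- function(p_disease, p_other) {
  if (any(p_disease < 0 | p_disease > 1) || any(p_other < 0 | p_other > 1)) {
    stop("combine_mortality: probabilities must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_disease) * (1 - p_other)
}

#' Per-cycle discount factor
#'
#' \eqn{(1 + r)^{-c \cdot d / 365.25}} for cycle index `c`, annual rate `r`,
#' cycle length `d` days: continuous-age compounding of the annual rate.
#'
#' @param cycle Cycle index (vectorized), `>= 0`.
#' @param annual_rate Annual discount rate, `>= 0`.
#' @param cycle_days Cycle length in days (default 21).
#' @return Discount factors in `(0, 1]`.
#' @export
discount_factor <- function(cycle, annual_rate, cycle_days = 21) {
  if (any(cycle < 0)) stop("discount_factor: cycle must be >= 0", call. = FALSE)
  if (annual_rate < 0) stop("discount_factor: rate must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-cycle * cycle_days / DAYS_PER_YEAR)
}

#' Half-cycle-corrected person-time of one occupancy column
#'
#' Trapezoidal sum \eqn{\sum_t (x_t + x_{t+1})/2}, in cycles.
#'
#' @param occupancy Numeric vector of per-cycle state occupancy (length >= 2).
#' @return Person-time in cycles.
#' @export
half_cycle_person_time <- function(occupancy) {
  n <- length(occupancy)
  if (n < 2) {
    stop("half_cycle_person_time: need at least two cycles", call. = FALSE)
  }
  sum((occupancy[-n] + occupancy[-1]) / 2)
}

# cumulative background survival at cycles 0..T for a cohort entering at
# start_age: product over elapsed cycles of (1 - per-cycle other-cause prob)
background_survival <- function(table, start_age, n_cycles, cycle_days = 21) {
  if (is.null(table)) return(rep(1, n_cycles + 1))
  ages <- start_age + (0:(n_cycles - 1)) * cycle_days / DAYS_PER_YEAR
  p <- other_cause_prob(table, ages, cycle_days)
  c(1, cumprod(1 - p))
}

#' Run the four-state cohort model
#'
#' Builds the per-cycle state occupancy trace for one strategy by the
#' partitioned-survival construction: the alive proportion follows the overall
#' survival curve, the progression-free proportion follows the PFS curve (both
#' multiplied by background survival from the life table), and progressed
#' disease is their difference, clamped at zero where the extrapolated curves
#' cross. The progression-free compartment is split into with/without adverse
#' events by a fixed fraction.
#'
#' The run stops at the earliest of: `settings$horizon`, the life table's
#' maximum age, or cohort death exceeding `1 - 1e-6`.
#'
#' @param pfs,os Survival models ([parametric_survival()] or [survival_fn()])
#'   for progression-free and overall survival, time in cycles.
#' @param table A [life_table()] for other-cause mortality, or `NULL`.
#' @param settings An [engine_settings()] object.
#' @param ae_split Fraction of the progression-free compartment in the
#'   with-adverse-events sub-state, in `[0, 1]`.
#' @return A `state_trace` data frame with columns `cycle`, `pfs_no_ae`,
#'   `pfs_ae`, `pd`, `death`, `discount_factor`. Attribute `"crossing_cycles"`
#'   records cycles where the PFS curve exceeded OS (clamped).
#' @export
run_cohort <- function(pfs, os, table = NULL, settings = engine_settings(),
                       ae_split = 0) {
  stopifnot(inherits(settings, "engine_settings"))
  if (ae_split < 0 || ae_split > 1) {
    stop("run_cohort: ae_split must lie in [0, 1]", call. = FALSE)
  }
  n_cycles <- settings$horizon
  if (!is.null(table)) {
    max_cycles <- ceiling((max(table$age) - settings$start_age) *
                            DAYS_PER_YEAR / settings$cycle_days)
    n_cycles <- min(n_cycles, max(max_cycles, 1L))
  }
  t <- 0:n_cycles
  s_os <- survival_at(os, t)
  s_pfs <- survival_at(pfs, t)
  bg <- background_survival(table, settings$start_age, n_cycles,
                            settings$cycle_days)
  alive <- s_os * bg
  pfs_raw <- s_pfs * bg
  crossing <- which(pfs_raw > alive + 1e-12) - 1L
  pfs_occ <- pmin(pfs_raw, alive)
  pd <- pmax(alive - pfs_occ, 0)
  death <- 1 - alive

  # truncate once the cohort is (numerically) extinct
  done <- which(death > 1 - 1e-6)
  if (length(done)) {
    keep <- seq_len(min(done[1], n_cycles + 1L))
    t <- t[keep]; alive <- alive[keep]; pfs_occ <- pfs_occ[keep]
    pd <- pd[keep]; death <- death[keep]
  }

  trace <- data.frame(
    cycle = t,
    pfs_no_ae = pfs_occ * (1 - ae_split),
    pfs_ae = pfs_occ * ae_split,
    pd = pd,
    death = death,
    discount_factor = discount_factor(t, settings$discount_rate,
                                      settings$cycle_days)
  )
  class(trace) <- c("state_trace", "data.frame")
  attr(trace, "crossing_cycles") <- crossing
  if (length(crossing)) {
    message("run_cohort: PFS curve exceeded OS from cycle ", crossing[1],
            "; progressed-disease occupancy clamped at 0 there")
  }
  trace
}

#' Accrue a discounted total over a state trace
#'
#' Sums occupancy x value x discount over cycles and states, with trapezoidal
#' half-cycle correction when enabled in `settings` (end-of-cycle convention
#' otherwise, i.e. cycles 1..T). Used identically for costs (value in $ per
#' cycle), QALYs (utility x cycle length in years) and life-years.
#'
#' @param trace A `state_trace` from [run_cohort()].
#' @param values Per-state value per cycle: either a named vector over the
#'   four states (constant in time) or a `(cycles x 4)` matrix with columns
#'   `pfs_no_ae`, `pfs_ae`, `pd`, `death`.
#' @param settings An [engine_settings()] object (discounting and the
#'   half-cycle flag are read from here).
#' @return Discounted total (scalar).
#' @export
accrue <- function(trace, values, settings) {
  n <- nrow(trace)
  occ <- as.matrix(trace[, STATE_NAMES])
  if (is.null(dim(values))) {
    if (!all(STATE_NAMES %in% names(values))) {
      stop("accrue: per-state values must be named over the four states",
           call. = FALSE)
    }
    values <- matrix(rep(values[STATE_NAMES], each = n), nrow = n,
                     dimnames = list(NULL, STATE_NAMES))
  }
  if (!all(dim(values) == dim(occ))) {
    stop("accrue: values matrix must be cycles x 4", call. = FALSE)
  }
  d <- trace$discount_factor
  per_cycle <- rowSums(occ * values) * d
  if (settings$half_cycle_correction) {
    w <- rep(1, n); w[c(1, n)] <- 0.5
    sum(w * per_cycle)
  } else {
    sum(per_cycle[-1])
  }
}

#' Write a state trace to CSV
#'
#' @param trace A `state_trace`.
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
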