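# Subgroup cost-effectiveness via published PFS hazard ratios.

#' Subgroup specification
#'
#' @param name Subgroup label.
#' @param hr Point-estimate PFS hazard ratio (treated vs control).
#' @param hr_low,hr_high Interval bounds, `0 < hr_low <= hr <= hr_high`.
#' @return A `subgroup_spec` list.
#' @export
subgroup_spec <- function(name, hr, hr_low = hr, hr_high = hr) {
  if (!(hr_low > 0 && hr_low <= hr && hr <= hr_high)) {
    stop("subgroup_spec: need 0 < hr_low <= hr <= hr_high", call. = FALSE)
  }
  structure(list(name = name, hr = hr, hr_low = hr_low, hr_high = hr_high),
            class = "subgroup_spec")
}

# treated-arm PFS for a given HR: proportional hazards applied to the
# control arm's baseline PFS curve
subgroup_pfs <- function(config, hr) {
  base <- config_surv_model(config$survival$bsc$pfs)
  ph_adjust(base, hr)
}

#' Incremental outcomes for one subgroup
#'
#' Subgroups share every input with the base case except the PFS hazard ratio:
#' the treated arm's PFS curve is reconstructed as \eqn{S_{control}(t)^{HR}}
#' (control-arm overall survival and all costs/utilities unchanged, since no
#' subgroup-specific values are published). The model is re-run at the point,
#' low and high HR; smaller HR means larger progression-free benefit, so the
#' INHB range runs from `hr_high` (low end) to `hr_low` (high end).
#'
#' @param config Validated configuration (two arms, the second is control).
#' @param spec A [subgroup_spec()].
#' @param psa_draws If `> 0`, also run a PSA of this size at the point HR and
#'   report the probability of cost-effectiveness at the configured WTP.
#' @param seed Seed for the optional PSA.
#' @return A `subgroup_result`: list with `name`, `hr`, `inhb`, `inhb_low`,
#'   `inhb_high`, `prob_ce` (`NA` if `psa_draws = 0`).
#' @export
subgroup_outcomes <- function(config, spec, psa_draws = 0, seed = 20220801) {
  stopifnot(inherits(spec, "subgroup_spec"))
  wtp <- config$settings$wtp
  arms <- names(config$strategies)
  control <- run_strategy(config, arms[2])
  inhb_at <- function(hr) {
    treated <- run_strategy(config, arms[1], pfs = subgroup_pfs(config, hr))
    incremental_measures(treated, control, wtp)$inhb
  }
  inhb <- inhb_at(spec$hr)
  lo <- inhb_at(spec$hr_high)   # larger HR -> smaller benefit
  hi <- inhb_at(spec$hr_low)
  prob_ce <- NA_real_
  if (psa_draws > 0) {
    cfg <- config
    cfg$subgroup_hr <- spec$hr
    samples <- run_psa_subgroup(cfg, psa_draws, seed)
    prob_ce <- ceac(samples, wtp)$prob_treated
  }
  structure(list(name = spec$name, hr = spec$hr,
                 inhb = inhb, inhb_low = min(lo, hi), inhb_high = max(lo, hi),
                 prob_ce = prob_ce),
            class = "subgroup_result")
}

# PSA variant with the treated arm's PFS pinned to the HR-adjusted curve
run_psa_subgroup <- function(config, n, seed) {
  stopifnot(!is.null(config$subgroup_hr))
  set.seed(seed)
  paths <- vapply(config$psa, `[[`, character(1), "path")
  params <- matrix(NA_real_, n, length(paths), dimnames = list(NULL, paths))
  for (j in seq_along(config$psa)) {
    e <- config$psa[[j]]
    x <- sample_parameter(e, n)
    if (!is.null(e$min)) x <- pmax(x, e$min)
    if (!is.null(e$max)) x <- pmin(x, e$max)
    params[, j] <- x
  }
  arms <- names(config$strategies)
  dc <- du <- rep(NA_real_, n)
  failed <- 0L
  for (i in seq_len(n)) {
    cfg <- config
    for (j in seq_along(paths)) {
      cfg <- set_config_value(cfg, paths[j], unname(params[i, j]))
    }
    res <- tryCatch({
      treated <- run_strategy(cfg, arms[1],
                              pfs = subgroup_pfs(cfg, cfg$subgroup_hr))
      control <- run_strategy(cfg, arms[2])
      incremental_measures(treated, control, cfg$settings$wtp)
    }, error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L
    else { dc[i] <- res$delta_cost; du[i] <- res$delta_qaly }
  }
  keep <- !is.na(dc)
  structure(list(
    draws = data.frame(draw = which(keep), delta_cost = dc[keep],
                       delta_qaly = du[keep]),
    params = params, seed = seed, n = n, n_failed = failed
  ), class = "psa_samples")
}

#' Run all configured subgroups
#'
#' @param config Validated configuration; `config$subgroups` is a list of
#'   entries with `name`, `hr`, `hr_low`, `hr_high`.
#' @inheritParams subgroup_outcomes
#' @return Data frame `name, hr, inhb, inhb_low, inhb_high, prob_ce`.
#' @export
run_subgroups <- function(config, psa_draws = 0, seed = 20220801) {
  if (!length(config$subgroups)) {
    stop("run_subgroups: config$subgroups is empty", call. = FALSE)
  }
  rows <- lapply(config$subgroups, function(s) {
    r <- subgroup_outcomes(config,
                           subgroup_spec(s$name, s$hr, s$hr_low, s$hr_high),
                           psa_draws, seed)
    data.frame(name = r$name, hr = r$hr, inhb = r$inhb,
               inhb_low = r$inhb_low, inhb_high = r$inhb_high,
               prob_ce = r$prob_ce)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
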