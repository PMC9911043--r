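# One-way (tornado) and probabilistic sensitivity analyses; CEAC.

#' Get / set a configuration value by dot-separated path
#'
#' Parameter paths such as `"costs.drug.capecitabine"` address leaves of the
#' nested configuration list; they are the handles used by the sensitivity
#' machinery.
#'
#' @param config Configuration list.
#' @param path Dot-separated path string.
#' @param value Replacement value (for `set_config_value`).
#' @return The value at `path`, or the modified configuration.
#' @export
get_config_value <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  tryCatch(config[[keys]], error = function(e) NULL)
}

#' @rdname get_config_value
#' @export
set_config_value <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (is.null(get_config_value(config, path))) {
    stop("set_config_value: unknown path '", path, "'", call. = FALSE)
  }
  config[[keys]] <- value
  config
}

#' One-way sensitivity range
#'
#' The +/-20% band around a baseline used for the tornado analysis.
#'
#' @param baseline Baseline value (finite).
#' @param frac Relative half-width (default 0.2).
#' @return Numeric vector `c(low, high)`.
#' @export
owsa_range <- function(baseline, frac = 0.2) {
  stopifnot(is.finite(baseline))
  c(low = (1 - frac) * baseline, high = (1 + frac) * baseline)
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full two-strategy comparison with each parameter at its low and
#' high bound, all others held at baseline, and ranks parameters by the spread
#' of the resulting ICUR. A parameter whose extremes leave the model unchanged
#' has spread exactly 0. Failures at an extreme are flagged in the `error`
#' column rather than dropped.
#'
#' @param config Validated configuration; `config$owsa` holds the parameter
#'   list (entries with `path`, `low`, `high`), as built by
#'   [baseline_fixture()].
#' @param parameters Optional subset: character vector of paths.
#' @param top Optionally keep only the `top` widest entries (e.g. 20).
#' @return Data frame `parameter, low, high, icur_low, icur_high, spread,
#'   error`, sorted by spread descending.
#' @export
run_owsa <- function(config, parameters = NULL, top = NULL) {
  entries <- config$owsa
  if (!length(entries)) stop("run_owsa: config$owsa is empty", call. = FALSE)
  paths <- vapply(entries, `[[`, character(1), "path")
  if (!is.null(parameters)) {
    keep <- paths %in% parameters
    entries <- entries[keep]; paths <- paths[keep]
  }
  eval_at <- function(path, value) {
    tryCatch(run_base_case(set_config_value(config, path, value))$comparison$icur,
             error = function(e) NA_real_)
  }
  lo <- hi <- numeric(length(entries))
  for (i in seq_along(entries)) {
    lo[i] <- eval_at(entries[[i]]$path, entries[[i]]$low)
    hi[i] <- eval_at(entries[[i]]$path, entries[[i]]$high)
  }
  out <- data.frame(
    parameter = paths,
    low = vapply(entries, `[[`, numeric(1), "low"),
    high = vapply(entries, `[[`, numeric(1), "high"),
    icur_low = lo, icur_high = hi,
    spread = abs(hi - lo),
    error = is.na(lo) | is.na(hi)
  )
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top)) out <- utils::head(out, top)
  out
}

#' Sampling distribution for one probabilistic-sensitivity parameter
#'
#' @param kind `"beta"`, `"gamma"` or `"fixed"`.
#' @param ... For beta: `alpha`, `beta`; for gamma: `shape`, `rate`
#'   (mean = shape/rate); for fixed: `value`.
#' @return A `psa_distribution` list.
#' @export
psa_distribution <- function(kind = c("beta", "gamma", "fixed"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  ok <- switch(kind,
    beta  = !is.null(p$alpha) && !is.null(p$beta) && p$alpha > 0 && p$beta > 0,
    gamma = !is.null(p$shape) && !is.null(p$rate) && p$shape > 0 && p$rate > 0,
    fixed = !is.null(p$value)
  )
  if (!ok) stop("psa_distribution: invalid parameters for kind '", kind, "'",
                call. = FALSE)
  structure(c(list(kind = kind), p), class = "psa_distribution")
}

#' Analytic mean of a PSA distribution
#'
#' @param dist A `psa_distribution` (or a config `psa` entry list).
#' @return The distribution mean.
#' @export
dist_mean <- function(dist) {
  switch(dist$kind,
    beta  = dist$alpha / (dist$alpha + dist$beta),
    gamma = dist$shape / dist$rate,
    fixed = dist$value
  )
}

#' Draw from a PSA distribution
#'
#' Beta draws lie in (0, 1); gamma draws are positive with mean shape/rate;
#' fixed always returns its value. Uses the current RNG stream.
#'
#' @param dist A `psa_distribution` (or a config `psa` entry list).
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_parameter <- function(dist, n = 1) {
  switch(dist$kind,
    beta  = stats::rbeta(n, dist$alpha, dist$beta),
    gamma = stats::rgamma(n, shape = dist$shape, rate = dist$rate),
    fixed = rep(dist$value, n),
    stop("sample_parameter: unknown kind '", dist$kind, "'", call. = FALSE)
  )
}

#' Audit PSA distribution means against baselines
#'
#' Every sampled parameter's analytic mean must match the baseline value it
#' replaces. Rounded published parameters can silently shift a mean; this
#' audit catches that at load time.
#'
#' @param config Configuration with a `psa` block.
#' @param tol Relative tolerance (default 0.01).
#' @return Data frame `path, baseline, mean, rel_err, ok` (invisible if all
#'   pass); errors if any entry exceeds `tol`.
#' @export
audit_distributions <- function(config, tol = 0.01) {
  rows <- lapply(config$psa, function(e) {
    base <- get_config_value(config, e$path)
    m <- dist_mean(e)
    rel <- if (base == 0) abs(m) else abs(m - base) / abs(base)
    data.frame(path = e$path, baseline = base, mean = m, rel_err = rel)
  })
  out <- do.call(rbind, rows)
  out$ok <- out$rel_err <= tol
  if (any(!out$ok)) {
    bad <- out[!out$ok, ]
    stop("audit_distributions: distribution mean deviates from baseline by >",
         tol * 100, "% for: ",
         paste(sprintf("%s (%.3g%%)", bad$path, 100 * bad$rel_err),
               collapse = ", "),
         call. = FALSE)
  }
  invisible(out)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` independent parameter vectors from the configured distributions,
#' re-runs the full two-strategy model per draw and records the incremental
#' cost and QALYs. Draws are clamped to a distribution's declared `min`/`max`
#' bounds where present (used for the discount rate, whose published beta
#' distribution has support wider than the admissible range). Failed draws are
#' excluded and counted.
#'
#' @param config Validated configuration; `config$psa` lists the sampled
#'   parameters.
#' @param n Number of Monte Carlo draws (the reference analysis uses 10000).
#' @param seed Integer seed; identical seeds give identical sample sets.
#' @return A `psa_samples` object: list with `draws` (data frame `draw,
#'   delta_cost, delta_qaly`), `params` (matrix of sampled values), `seed`,
#'   `n`, `n_failed`.
#' @export
run_psa <- function(config, n = 1000, seed = 20220801) {
  stopifnot(n >= 1)
  set.seed(seed)
  paths <- vapply(config$psa, `[[`, character(1), "path")
  params <- matrix(NA_real_, n, length(paths),
                   dimnames = list(NULL, paths))
  for (j in seq_along(config$psa)) {
    e <- config$psa[[j]]
    x <- sample_parameter(e, n)
    if (!is.null(e$min)) x <- pmax(x, e$min)
    if (!is.null(e$max)) x <- pmin(x, e$max)
    params[, j] <- x
  }
  dc <- du <- rep(NA_real_, n)
  failed <- 0L
  for (i in seq_len(n)) {
    cfg <- config
    for (j in seq_along(paths)) {
      cfg <- set_config_value(cfg, paths[j], unname(params[i, j]))
    }
    res <- tryCatch(run_base_case(cfg), error = function(e) NULL)
    if (is.null(res)) {
      failed <- failed + 1L
    } else {
      dc[i] <- res$comparison$delta_cost
      du[i] <- res$comparison$delta_qaly
    }
  }
  keep <- !is.na(dc)
  structure(list(
    draws = data.frame(draw = which(keep), delta_cost = dc[keep],
                       delta_qaly = du[keep]),
    params = params, seed = seed, n = n, n_failed = failed
  ), class = "psa_samples")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `w`, the fraction of PSA draws with
#' positive incremental net monetary benefit, i.e.
#' \eqn{\Delta U \cdot w - \Delta C > 0}.
#'
#' @param samples A `psa_samples` object from [run_psa()].
#' @param wtp_grid Vector of willingness-to-pay thresholds ($/QALY).
#' @return Data frame `wtp, prob_treated, prob_control`
#'   (`prob_control = 1 - prob_treated`).
#' @export
ceac <- function(samples, wtp_grid) {
  stopifnot(inherits(samples, "psa_samples"), length(wtp_grid) >= 1)
  d <- samples$draws
  if (!nrow(d)) stop("ceac: empty sample set", call. = FALSE)
  p <- vapply(wtp_grid, function(w) {
    mean(d$delta_qaly * w - d$delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, prob_treated = p, prob_control = 1 - p)
}

#' @export
print.psa_samples <- function(x, ...) {
  cat("<psa_samples>", nrow(x$draws), "of", x$n, "draws (seed", x$seed,
      ",", x$n_failed, "failed)\n")
  cat("  mean delta cost $", round(mean(x$draws$delta_cost)),
      ", mean delta QALYs ", signif(mean(x$draws$delta_qaly), 4), "\n",
      sep = "")
  invisible(x)
}
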