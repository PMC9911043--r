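# Parametric survival laws on the model-cycle time scale (1 cycle = 21 days).

SURV_FAMILIES <- c("exponential", "weibull", "loglogistic", "lognormal", "gompertz")

# S() is floored here before any ratio is taken.
.SURV_FLOOR <- 1e-12

#' Construct a parametric survival model
#'
#' Represents one of the five survival families used to extrapolate
#' progression-free and overall survival beyond trial follow-up. Time is
#' measured in model cycles (one cycle = 21 days) throughout.
#'
#' Parameterizations (all times `t` in cycles):
#' \describe{
#'   \item{exponential}{`rate` \eqn{\rho > 0}; \eqn{S(t) = e^{-\rho t}}.}
#'   \item{weibull}{`shape` \eqn{k > 0}, `scale` \eqn{\sigma > 0};
#'     \eqn{S(t) = e^{-(t/\sigma)^k}}.}
#'   \item{loglogistic}{`lambda` \eqn{\lambda > 0} (scale-rate), `gamma`
#'     \eqn{\gamma > 0} (shape); \eqn{S(t) = 1/(1 + \lambda t^{\gamma})}.}
#'   \item{lognormal}{`meanlog`, `sdlog` \eqn{> 0}; \eqn{S(t) = 1 - \Phi((\log t
#'     - \mu)/\sigma)}.}
#'   \item{gompertz}{`shape` \eqn{c} (any real), `rate` \eqn{b > 0}; hazard
#'     \eqn{h(t) = b e^{c t}}, so \eqn{S(t) = \exp(-b/c\,(e^{ct} - 1))}, with
#'     the exponential limit at \eqn{c = 0}.}
#' }
#'
#' @param family One of `"exponential"`, `"weibull"`, `"loglogistic"`,
#'   `"lognormal"`, `"gompertz"`.
#' @param ... Named parameters for the family (see Details), e.g.
#'   `parametric_survival("loglogistic", lambda = 0.11712, gamma = 0.80840)`.
#' @return An object of class `parametric_survival`.
#' @examples
#' m <- parametric_survival("loglogistic", lambda = 0.11712, gamma = 0.80840)
#' survival_at(m, 10)
#' median_time(m)
#' @export
parametric_survival <- function(family, ...) {
  family <- match.arg(family, SURV_FAMILIES)
  params <- list(...)
  need <- surv_param_names(family)
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("parametric_survival: missing parameter(s) for ", family, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params <- params[need]
  for (p in need) {
    v <- params[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parametric_survival: parameter '", p, "' must be a finite scalar",
           call. = FALSE)
    }
    # meanlog (lognormal) and shape (gompertz) live on the whole real line
    free <- (family == "lognormal" && p == "meanlog") ||
      (family == "gompertz" && p == "shape")
    if (!free && v <= 0) {
      stop("parametric_survival: parameter '", p, "' must be > 0 for family '",
           family, "'", call. = FALSE)
    }
  }
  structure(list(family = family, params = params),
            class = "parametric_survival")
}

surv_param_names <- function(family) {
  switch(family,
    exponential = "rate",
    weibull     = c("shape", "scale"),
    loglogistic = c("lambda", "gamma"),
    lognormal   = c("meanlog", "sdlog"),
    gompertz    = c("shape", "rate")
  )
}

#' Wrap an arbitrary survival function
#'
#' Lifts a plain function `t -> S(t)` (time in cycles) into an object usable
#' anywhere a [parametric_survival()] model is accepted, e.g. the
#' hazard-ratio-adjusted curves built by [ph_adjust()].
#'
#' @param fn A vectorized function of time returning survival probabilities.
#' @return An object of class `survival_fn`.
#' @export
survival_fn <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(fn = fn), class = "survival_fn")
}

#' Evaluate a survival curve
#'
#' @param model A [parametric_survival()] or [survival_fn()] object.
#' @param t Time(s) in model cycles, `>= 0`.
#' @return `S(t)`, in `[0, 1]`, vectorized over `t`.
#' @export
survival_at <- function(model, t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("survival_at: t must be finite and >= 0", call. = FALSE)
  }
  UseMethod("survival_at")
}

#' @export
survival_at.parametric_survival <- function(model, t) {
  p <- model$params
  s <- switch(model$family,
    exponential = exp(-p$rate * t),
    weibull     = exp(-(t / p$scale)^p$shape),
    loglogistic = 1 / (1 + p$lambda * t^p$gamma),
    lognormal   = stats::plnorm(t, p$meanlog, p$sdlog, lower.tail = FALSE),
    gompertz    = {
      if (abs(p$shape) < 1e-10) exp(-p$rate * t)
      else exp(-(p$rate / p$shape) * expm1(p$shape * t))
    }
  )
  # t = 0 with gamma < 1 gives 0^gamma = 0 -> S = 1 already; just clamp range
  pmin(pmax(s, 0), 1)
}

#' @export
survival_at.survival_fn <- function(model, t) {
  s <- model$fn(t)
  if (any(!is.finite(s)) || any(s < -1e-9) || any(s > 1 + 1e-9)) {
    stop("survival_fn returned values outside [0, 1]", call. = FALSE)
  }
  pmin(pmax(s, 0), 1)
}

#' Log-density of a parametric survival model
#'
#' Used by the censored-likelihood fitter; stable in the tails.
#' @param model A [parametric_survival()] object.
#' @param t Times in cycles, `> 0`.
#' @return `log f(t)`.
#' @keywords internal
surv_logdensity <- function(model, t) {
  p <- model$params
  switch(model$family,
    exponential = stats::dexp(t, p$rate, log = TRUE),
    weibull     = stats::dweibull(t, p$shape, p$scale, log = TRUE),
    loglogistic = log(p$lambda) + log(p$gamma) + (p$gamma - 1) * log(t) -
      2 * log1p(p$lambda * t^p$gamma),
    lognormal   = stats::dlnorm(t, p$meanlog, p$sdlog, log = TRUE),
    gompertz    = {
      # log h(t) + log S(t)
      lh <- log(p$rate) + p$shape * t
      ls <- if (abs(p$shape) < 1e-10) -p$rate * t
            else -(p$rate / p$shape) * expm1(p$shape * t)
      lh + ls
    }
  )
}

#' Quantile (inverse survival) of a parametric model
#'
#' Returns the time `t` with `S(t) = s`. Used by the pseudo-IPD simulator
#' (inverse-CDF sampling) and by [median_time()].
#'
#' @param model A [parametric_survival()] object.
#' @param s Survival probabilities in `(0, 1)`.
#' @return Times in cycles.
#' @export
surv_inverse <- function(model, s) {
  if (any(s <= 0) || any(s >= 1)) {
    stop("surv_inverse: s must lie strictly in (0, 1)", call. = FALSE)
  }
  p <- model$params
  switch(model$family,
    exponential = -log(s) / p$rate,
    weibull     = p$scale * (-log(s))^(1 / p$shape),
    loglogistic = ((1 - s) / (p$lambda * s))^(1 / p$gamma),
    lognormal   = stats::qlnorm(s, p$meanlog, p$sdlog, lower.tail = FALSE),
    gompertz    = {
      if (abs(p$shape) < 1e-10) return(-log(s) / p$rate)
      arg <- 1 - (p$shape / p$rate) * log(s)
      if (any(arg <= 0)) {
        stop("surv_inverse: survival level not attained by this Gompertz model",
             call. = FALSE)
      }
      log(arg) / p$shape
    }
  )
}

#' Median survival time
#'
#' Time at which the curve crosses 0.5; log-logistic closed form
#' \eqn{(1/\lambda)^{1/\gamma}}.
#'
#' @inheritParams survival_at
#' @return Median time in cycles.
#' @export
median_time <- function(model) {
  UseMethod("median_time")
}

#' @export
median_time.parametric_survival <- function(model) {
  if (model$family == "gompertz") {
    p <- model$params
    if (p$shape < 0) {
      # improper distribution: S(Inf) = exp(rate/shape) may exceed 0.5
      if (exp(p$rate / p$shape) > 0.5) {
        stop("median_time: survival never reaches 0.5 for this model",
             call. = FALSE)
      }
    }
  }
  surv_inverse(model, 0.5)
}

#' @export
median_time.survival_fn <- function(model) {
  f <- function(t) survival_at(model, t) - 0.5
  upper <- 1
  while (f(upper) > 0 && upper < 1e8) upper <- upper * 2
  if (f(upper) > 0) {
    stop("median_time: survival never reaches 0.5 within numeric range",
         call. = FALSE)
  }
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' Per-cycle event probability from a survival curve
#'
#' The probability of the event occurring during cycle interval
#' `[cycle, cycle + 1)` conditional on being event-free at its start:
#' \eqn{1 - S(c+1)/S(c)}. Survival is floored at `1e-12` before the ratio; a
#' floored denominator returns 1 with a warning.
#'
#' @param model A [parametric_survival()] or [survival_fn()] object.
#' @param cycle Integer cycle index (vectorized), `>= 0`.
#' @return Probabilities in `[0, 1]`.
#' @export
per_cycle_event_prob <- function(model, cycle) {
  if (any(cycle < 0) || any(cycle != floor(cycle))) {
    stop("per_cycle_event_prob: cycle must be a non-negative integer",
         call. = FALSE)
  }
  s0 <- survival_at(model, cycle)
  s1 <- survival_at(model, cycle + 1)
  if (any(s0 <= .SURV_FLOOR)) {
    warning("per_cycle_event_prob: survival exhausted (S <= 1e-12); ",
            "returning event probability 1 at those cycles", call. = FALSE)
  }
  p <- 1 - s1 / pmax(s0, .SURV_FLOOR)
  pmin(pmax(p, 0), 1)
}

# ---- maximum-likelihood fitting to right-censored pseudo-IPD ----------------

# map params to/from an unconstrained optimizer scale
.surv_to_unconstrained <- function(family, params) {
  v <- unlist(params)
  if (family == "lognormal") c(v[["meanlog"]], log(v[["sdlog"]]))
  else if (family == "gompertz") c(v[["shape"]], log(v[["rate"]]))
  else log(v)
}

.surv_from_unconstrained <- function(family, x) {
  nm <- surv_param_names(family)
  v <- switch(family,
    lognormal = c(x[1], exp(x[2])),
    gompertz  = c(x[1], exp(x[2])),
    exp(x)
  )
  stats::setNames(as.list(v), nm)
}

.surv_init <- function(family, time, event) {
  te <- time[event == 1]
  if (!length(te)) te <- time
  te <- pmax(te, 1e-8)
  lt <- log(te)
  m <- mean(lt); s <- max(stats::sd(lt), 0.1)
  if (is.na(s)) s <- 1
  switch(family,
    exponential = list(rate = sum(event) / sum(time)),
    weibull     = list(shape = 1.2 / s, scale = exp(m)),
    loglogistic = {
      g <- pi / (s * sqrt(3))
      list(lambda = exp(-g * m), gamma = g)
    },
    lognormal   = list(meanlog = m, sdlog = s),
    gompertz    = list(shape = 0.01, rate = max(sum(event) / sum(time), 1e-6))
  )
}

#' Fit a parametric survival model to right-censored pseudo-IPD
#'
#' Maximum-likelihood fit of one family to (time, event) records, the standard
#' input when individual patient data are reconstructed from published
#' Kaplan-Meier curves. Censored records contribute `log S(t)`, events
#' `log f(t)`. The exponential family uses its closed-form MLE; the others are
#' fitted by quasi-Newton optimization on an unconstrained parameter scale.
#'
#' @param time Observation times in cycles, `> 0`.
#' @param event Event indicator (1 = event, 0 = right-censored).
#' @param family Survival family to fit.
#' @return A `surv_fit` object: list with `model` ([parametric_survival()]),
#'   `loglik`, `aic` (\eqn{-2\ell + 2k}), `bic` (\eqn{-2\ell + k\log n}),
#'   `n`, `n_events`, `convergence`.
#' @seealso [select_model()], [simulate_ipd()]
#' @export
fit_km <- function(time, event, family) {
  family <- match.arg(family, SURV_FAMILIES)
  stopifnot(length(time) == length(event))
  if (length(time) < 10) {
    stop("fit_km: need at least 10 observations", call. = FALSE)
  }
  if (any(time <= 0) || any(!event %in% c(0, 1))) {
    stop("fit_km: times must be > 0 and event must be 0/1", call. = FALSE)
  }
  if (sum(event) < 1) {
    stop("fit_km: all observations censored; cannot fit", call. = FALSE)
  }
  n <- length(time)
  k <- length(surv_param_names(family))

  negll <- function(x) {
    pars <- .surv_from_unconstrained(family, x)
    m <- structure(list(family = family, params = pars),
                   class = "parametric_survival")
    ll <- sum(surv_logdensity(m, time[event == 1])) +
      sum(log(pmax(survival_at(m, time[event == 0]), .SURV_FLOOR)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  if (family == "exponential") {
    rate <- sum(event) / sum(time)
    model <- parametric_survival("exponential", rate = rate)
    ll <- -negll(log(rate))
    conv <- 0L
  } else {
    x0 <- .surv_to_unconstrained(family, .surv_init(family, time, event))
    opt <- stats::optim(x0, negll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    opt2 <- tryCatch(
      stats::optim(opt$par, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) opt)
    if (opt2$value <= opt$value) opt <- opt2
    if (opt$convergence != 0 && opt$value >= 1e10) {
      stop("fit_km: optimizer failed to converge for family '", family,
           "' (code ", opt$convergence, ", nll ", signif(opt$value, 6), ")",
           call. = FALSE)
    }
    pars <- .surv_from_unconstrained(family, opt$par)
    model <- do.call(parametric_survival, c(list(family), pars))
    ll <- -opt$value
    conv <- opt$convergence
  }

  structure(list(
    model = model, family = family,
    loglik = ll,
    aic = -2 * ll + 2 * k,
    bic = -2 * ll + k * log(n),
    n = n, n_events = sum(event), convergence = conv
  ), class = "surv_fit")
}

#' Fit all five families to the same data
#'
#' @inheritParams fit_km
#' @param families Families to fit (default all five).
#' @return Named list of `surv_fit` objects.
#' @export
fit_all_families <- function(time, event, families = SURV_FAMILIES) {
  stats::setNames(lapply(families, function(f) fit_km(time, event, f)),
                  families)
}

#' Select the best-fitting survival model
#'
#' Minimal AIC wins; ties (within `1e-9`) are broken by minimal BIC, then by
#' the conventional family order exponential, Weibull, log-logistic,
#' lognormal, Gompertz. The full ranking is attached as attribute `"ranking"`.
#'
#' @param fits A list of `surv_fit` objects from [fit_km()] on the same data.
#' @return The selected `surv_fit`.
#' @export
select_model <- function(fits) {
  if (!length(fits)) stop("select_model: empty fit list", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "surv_fit")))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  fam <- vapply(fits, `[[`, character(1), "family")
  ord <- order(aic, bic, match(fam, SURV_FAMILIES))
  ranking <- data.frame(family = fam[ord], aic = aic[ord], bic = bic[ord],
                        row.names = NULL)
  best <- fits[[ord[1]]]
  attr(best, "ranking") <- ranking
  best
}

#' Apply a proportional-hazards adjustment to a survival curve
#'
#' Returns the curve \eqn{t \mapsto S(t)^{HR}}, the standard construction for
#' subgroup analysis when only a hazard ratio relative to a reference arm is
#' published. Note the result generally leaves the parametric family.
#'
#' @param model A [parametric_survival()] or [survival_fn()] object.
#' @param hr Hazard ratio, `> 0`.
#' @return A [survival_fn()] object.
#' @export
ph_adjust <- function(model, hr) {
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0) {
    stop("ph_adjust: hr must be a positive finite scalar", call. = FALSE)
  }
  force(model)
  survival_fn(function(t) survival_at(model, t)^hr)
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat("<parametric_survival>", x$family, "(",
      paste(names(x$params), "=", signif(unlist(x$params), 6),
            collapse = ", "),
      "), time in 21-day cycles\n")
  invisible(x)
}

#' @export
print.surv_fit <- function(x, ...) {
  cat("<surv_fit>", x$family, " loglik =", signif(x$loglik, 8),
      " AIC =", signif(x$aic, 8), " BIC =", signif(x$bic, 8),
      " (n =", x$n, ", events =", x$n_events, ")\n")
  print(x$model)
  invisible(x)
}
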