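# Configuration I/O and validation.

#' Validate a model configuration
#'
#' Checks structural completeness (every required block present), value bounds
#' (proportions, incidences and utilities in `[0, 1]`; costs non-negative;
#' discount rate in `[0, 0.08]`; survival parameters positive) and audits every
#' sampling distribution's analytic mean against the baseline it replaces
#' (hard error above `audit_tol`). All offending keys are reported together.
#'
#' @param config Configuration list (see [baseline_fixture()] for the schema).
#' @param audit_tol Hard-error tolerance for the distribution-mean audit
#'   (default 0.05).
#' @return The configuration, invisibly classed `cea_config`.
#' @export
validate_config <- function(config, audit_tol = 0.05) {
  problems <- character(0)
  need <- c("settings", "patient", "survival", "utility", "costs",
            "strategies", "assumptions")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop("validate_config: missing block(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  chk01 <- function(value, key) {
    if (is.null(value) || !is.numeric(value) || value < 0 || value > 1) {
      problems <<- c(problems, paste0(key, " must lie in [0, 1]"))
    }
  }
  chk_pos <- function(value, key, strict = FALSE) {
    if (is.null(value) || !is.numeric(value) || value < 0 ||
        (strict && value == 0)) {
      problems <<- c(problems,
                     paste0(key, if (strict) " must be > 0" else
                       " must be >= 0"))
    }
  }
  s <- config$settings
  if (s$discount_rate < 0 || s$discount_rate > 0.08) {
    problems <- c(problems, "settings.discount_rate must lie in [0, 0.08]")
  }
  chk_pos(s$wtp, "settings.wtp", strict = TRUE)
  chk_pos(s$start_age, "settings.start_age", strict = TRUE)
  chk_pos(config$patient$weight, "patient.weight", strict = TRUE)
  chk_pos(config$patient$bsa, "patient.bsa", strict = TRUE)
  for (k in c("pfs", "pd", "death", "ae_disutility")) {
    chk01(config$utility[[k]], paste0("utility.", k))
  }
  for (arm in names(config$survival)) {
    for (curve in c("os", "pfs")) {
      blk <- config$survival[[arm]][[curve]]
      if (is.null(blk$family)) {
        problems <- c(problems,
                      paste0("survival.", arm, ".", curve, ".family missing"))
        next
      }
      for (p in setdiff(names(blk), "family")) {
        free <- (blk$family == "lognormal" && p == "meanlog") ||
          (blk$family == "gompertz" && p == "shape")
        if (!free && blk[[p]] <= 0) {
          problems <- c(problems,
                        paste0("survival.", arm, ".", curve, ".", p,
                               " must be > 0"))
        }
      }
    }
  }
  for (k in names(config$costs$drug)) {
    chk_pos(config$costs$drug[[k]], paste0("costs.drug.", k))
  }
  for (k in c("radiotherapy", "bsc_per_cycle", "imaging", "lab")) {
    chk_pos(config$costs[[k]], paste0("costs.", k))
  }
  for (k in names(config$costs$ae)) {
    chk_pos(config$costs$ae[[k]], paste0("costs.ae.", k))
  }
  for (arm in names(config$strategies)) {
    st <- config$strategies[[arm]]
    for (k in names(st$concomitant)) {
      chk01(st$concomitant[[k]],
            paste0("strategies.", arm, ".concomitant.", k))
    }
    for (k in names(st$subsequent)) {
      chk01(st$subsequent[[k]],
            paste0("strategies.", arm, ".subsequent.", k))
    }
    for (k in names(st$ae_incidence)) {
      chk01(st$ae_incidence[[k]],
            paste0("strategies.", arm, ".ae_incidence.", k))
    }
  }
  if (!is.null(config$life_table)) {
    lt <- try(life_table(unlist(config$life_table$age),
                         unlist(config$life_table$qx)), silent = TRUE)
    if (inherits(lt, "try-error")) {
      problems <- c(problems, paste0("life_table: ",
                                     attr(lt, "condition")$message))
    }
  }
  if (length(problems)) {
    stop("validate_config: ", length(problems), " problem(s):\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  if (length(config$psa)) audit_distributions(config, tol = audit_tol)
  class(config) <- unique(c("cea_config", class(config)))
  invisible(config)
}

#' Load and validate a configuration from JSON
#'
#' @param path Path to a JSON configuration (schema of [baseline_fixture()]).
#' @param audit_tol Passed to [validate_config()].
#' @return The validated configuration list.
#' @export
load_config <- function(path, audit_tol = 0.05) {
  if (!file.exists(path)) {
    stop("load_config: no such file: ", path, call. = FALSE)
  }
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  validate_config(cfg, audit_tol = audit_tol)
}

#' Write a configuration to JSON
#'
#' @param config Configuration list.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  class(config) <- "list"
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
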