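# Model inputs: transition probabilities, costs, utilities, disutilities,
# and the settings that select between scenarios and costing perspectives.

#' Convert a cumulative risk over a horizon to a constant annual probability
#'
#' Solves `1 - (1 - p)^h = P` for the per-cycle probability `p`, i.e. the
#' constant annual probability that compounds to a reported multi-year
#' cumulative risk `P` over `h` years. Used to turn 2-year repair failure
#' rates and 5/10/15-year osteoarthritis endpoints into annual cycle
#' probabilities.
#'
#' @param cumulative_prob Cumulative probability over the horizon, in `[0, 1)`.
#' @param horizon_years Length of the horizon in years (>= 1). May be
#'   non-integer.
#' @return The equivalent constant annual probability, same length as the
#'   longer of the two arguments.
#' @examples
#' endpoint_to_annual_prob(0.174, 2)  # ~0.0912
#' endpoint_to_annual_prob(0.056, 2)  # ~0.0284
#' @export
endpoint_to_annual_prob <- function(cumulative_prob, horizon_years) {
  if (any(!is.finite(cumulative_prob)) || any(cumulative_prob < 0) ||
      any(cumulative_prob >= 1)) {
    stop("`cumulative_prob` must lie in [0, 1)", call. = FALSE)
  }
  if (any(!is.finite(horizon_years)) || any(horizon_years < 1)) {
    stop("`horizon_years` must be >= 1", call. = FALSE)
  }
  1 - (1 - cumulative_prob)^(1 / horizon_years)
}

#' Apply a relative risk to an annual transition probability
#'
#' Adjusts an annual probability by a relative risk, either directly on the
#' probability scale (`p * rr`, the default) or on the rate scale
#' (`1 - (1 - p)^rr`, exact if the relative risk acts on the instantaneous
#' hazard). The two agree to first order for small probabilities.
#'
#' @param p_annual Annual probability in `[0, 1]`.
#' @param rr Relative risk (> 0).
#' @param mode `"multiplicative"` (probability scale, default) or `"rate"`
#'   (hazard scale).
#' @return Adjusted annual probability.
#' @examples
#' rr_adjust_prob(0.1127, 0.55)                 # 0.0619849
#' rr_adjust_prob(0.1127, 0.55, mode = "rate")  # ~0.0636
#' @export
rr_adjust_prob <- function(p_annual, rr, mode = c("multiplicative", "rate")) {
  mode <- match.arg(mode)
  if (any(p_annual < 0) || any(p_annual > 1)) {
    stop("`p_annual` must lie in [0, 1]", call. = FALSE)
  }
  if (any(rr <= 0)) stop("`rr` must be positive", call. = FALSE)
  out <- if (mode == "multiplicative") p_annual * rr else 1 - (1 - p_annual)^rr
  if (any(out > 1)) {
    stop("adjusted probability exceeds 1; reduce `rr` or `p_annual`",
         call. = FALSE)
  }
  out
}

# Base-case inputs. Probabilities are per annual cycle, costs in 2021 USD,
# utilities per cycle, disutilities per procedure event.
.base_parameters <- function() {
  list(
    scenario          = "all_suture",
    setting           = "hospital",
    start_age         = 35,
    max_age           = 110,
    cohort_size       = 1000,
    p_fail_pm_annual  = 0.002,
    p_fail_mr_annual  = 0.0912,
    failure_window_years = 3,
    p_oa_pm_by_period = c("1-5" = 0.1127, "6-10" = 0.0351, "11+" = 0.0089),
    rr_oa_mr_vs_pm    = 0.55,
    p_oa_to_tkr_annual = 0.0227,
    p_tkr_revision_by_period = c("1-4" = 0.019, "5-9" = 0.01,
                                 "10" = 0.009, "11+" = 0.006),
    p_procedure_mortality = 0.003,
    cost_mr_index     = c(hospital = 4996, ASC = 3494),
    cost_pm_index_or_revision = c(hospital = 3433, ASC = 1931),
    cost_tkr          = 38916,
    cost_rtkr         = 46698,
    cost_oa_state_annual = 3486,
    u_no_oa           = 0.9,
    u_oa              = 0.69,
    u_post_tkr        = 0.835,
    u_post_rtkr       = 0.785,
    disutil_meniscal_procedure = 0.0077,
    disutil_tkr       = 0.025,
    disutil_rtkr      = 0.05,
    discount_rate_costs = 0.03,
    discount_rate_qalys = 0.03,
    wtp_threshold     = 100000,
    rr_mode           = "rate",
    rtkr_clock        = "since_primary",
    post_revision_progression = "comparator",
    within_cycle_correction = "half_cycle",
    discount_timing   = "midcycle"
  )
}

# MR annual failure probability per effectiveness scenario (converted from
# published 2-year failure rates).
.scenario_fail_mr <- c(all_suture = 0.0912, various_techniques = 0.0284)

#' Build a validated model parameter set
#'
#' Assembles the full set of model inputs -- transition probabilities, costs,
#' utilities, disutilities, discounting and structural switches -- starting
#' from the base case and applying overrides from a configuration list or a
#' JSON/YAML file with flat keys matching the parameter names. Unknown keys
#' are rejected.
#'
#' @param config Named list of overrides, or path to a JSON/YAML file
#'   containing one. A `scenario` key (`"all_suture"` or
#'   `"various_techniques"`) selects the meniscal-repair failure probability
#'   unless `p_fail_mr_annual` is overridden explicitly.
#' @param ... Additional overrides given directly as named arguments; these
#'   take precedence over `config`.
#' @return An object of class `meniscus_params`: a named list of validated
#'   model inputs.
#' @examples
#' p <- build_parameter_set()
#' p$p_fail_mr_annual
#' p60 <- build_parameter_set(list(start_age = 60, setting = "ASC"))
#' @export
build_parameter_set <- function(config = list(), ...) {
  if (is.character(config) && length(config) == 1) {
    config <- read_model_config(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a file path",
                             call. = FALSE)
  dots <- list(...)
  config[names(dots)] <- dots

  params <- .base_parameters()
  unknown <- setdiff(names(config), names(params))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    if (!sc %in% names(.scenario_fail_mr)) {
      stop("`scenario` must be one of: ",
           paste(names(.scenario_fail_mr), collapse = ", "), call. = FALSE)
    }
    params$scenario <- sc
    params$p_fail_mr_annual <- unname(.scenario_fail_mr[sc])
  }
  for (nm in setdiff(names(config), "scenario")) {
    base_val <- params[[nm]]
    val <- config[[nm]]
    if (is.numeric(base_val) && length(base_val) > 1) {
      # banded/by-setting vectors: accept full replacement, keep names
      val <- unlist(val)
      if (length(val) != length(base_val)) {
        stop("override for `", nm, "` must have length ", length(base_val),
             call. = FALSE)
      }
      if (is.null(names(val))) names(val) <- names(base_val)
      val <- val[names(base_val)]
    }
    params[[nm]] <- val
  }
  validate_parameter_set(params)
}

#' @rdname build_parameter_set
#' @param path Path to a `.json`, `.yaml` or `.yml` configuration file.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("config must be a .json, .yaml or .yml file", call. = FALSE)
  )
  as.list(cfg)
}

# Validates ranges and structural consistency; collects all offending fields
# into one error message.
validate_parameter_set <- function(params) {
  bad <- character(0)
  chk <- function(cond, msg) if (!isTRUE(all(cond))) bad <<- c(bad, msg)

  probs <- c("p_fail_pm_annual", "p_fail_mr_annual", "p_oa_to_tkr_annual",
             "p_procedure_mortality")
  for (nm in probs) {
    chk(is.numeric(params[[nm]]) && params[[nm]] >= 0 && params[[nm]] <= 1,
        paste0(nm, " must be a probability in [0, 1]"))
  }
  chk(all(params$p_oa_pm_by_period >= 0 & params$p_oa_pm_by_period <= 1),
      "p_oa_pm_by_period entries must be probabilities in [0, 1]")
  chk(all(params$p_tkr_revision_by_period >= 0 &
            params$p_tkr_revision_by_period <= 1),
      "p_tkr_revision_by_period entries must be probabilities in [0, 1]")
  chk(identical(names(params$p_oa_pm_by_period), c("1-5", "6-10", "11+")),
      "p_oa_pm_by_period must have bands 1-5, 6-10, 11+")
  chk(identical(names(params$p_tkr_revision_by_period),
                c("1-4", "5-9", "10", "11+")),
      "p_tkr_revision_by_period must have bands 1-4, 5-9, 10, 11+")
  chk(params$rr_oa_mr_vs_pm > 0, "rr_oa_mr_vs_pm must be positive")
  chk(max(params$p_oa_pm_by_period) * max(params$rr_oa_mr_vs_pm, 1) <= 1,
      "rr-adjusted OA probability exceeds 1")

  for (nm in c("u_no_oa", "u_oa", "u_post_tkr", "u_post_rtkr")) {
    chk(params[[nm]] >= 0 && params[[nm]] <= 1,
        paste0(nm, " must be a utility in [0, 1]"))
  }
  costs <- c("cost_mr_index", "cost_pm_index_or_revision", "cost_tkr",
             "cost_rtkr", "cost_oa_state_annual")
  for (nm in costs) chk(all(params[[nm]] >= 0), paste0(nm, " must be >= 0"))
  chk(all(c("hospital", "ASC") %in% names(params$cost_mr_index)) &&
        all(c("hospital", "ASC") %in% names(params$cost_pm_index_or_revision)),
      "index procedure costs must be named by setting (hospital, ASC)")
  for (nm in c("disutil_meniscal_procedure", "disutil_tkr", "disutil_rtkr")) {
    chk(params[[nm]] >= 0 && params[[nm]] <= 1,
        paste0(nm, " must lie in [0, 1]"))
  }
  chk(params$discount_rate_costs >= 0 && params$discount_rate_qalys >= 0,
      "discount rates must be >= 0")
  chk(params$setting %in% c("hospital", "ASC"),
      "setting must be 'hospital' or 'ASC'")
  chk(params$start_age >= 0 && params$start_age < params$max_age,
      "start_age must be non-negative and below max_age")
  chk(params$cohort_size > 0, "cohort_size must be positive")
  chk(params$failure_window_years >= 0,
      "failure_window_years must be >= 0 (Inf allowed)")
  chk(params$wtp_threshold >= 0, "wtp_threshold must be >= 0")
  chk(params$rr_mode %in% c("multiplicative", "rate"),
      "rr_mode must be 'multiplicative' or 'rate'")
  chk(params$rtkr_clock %in% c("since_primary", "since_tkr"),
      "rtkr_clock must be 'since_primary' or 'since_tkr'")
  chk(params$post_revision_progression %in% c("comparator", "arm"),
      "post_revision_progression must be 'comparator' or 'arm'")
  chk(params$within_cycle_correction %in% c("half_cycle", "trapezoid", "none"),
      "within_cycle_correction must be half_cycle, trapezoid or none")
  chk(params$discount_timing %in% c("midcycle", "end", "start"),
      "discount_timing must be midcycle, end or start")

  if (length(bad)) {
    stop("invalid parameter set:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(params, class = "meniscus_params")
}

# Procedure costs for the active costing perspective.
.proc_costs <- function(params) {
  s <- params$setting
  list(
    mr_index  = unname(params$cost_mr_index[s]),
    pm_index  = unname(params$cost_pm_index_or_revision[s]),
    revision  = unname(params$cost_pm_index_or_revision[s]),
    tkr       = params$cost_tkr,
    rtkr      = params$cost_rtkr,
    oa_annual = params$cost_oa_state_annual
  )
}

#' @export
print.meniscus_params <- function(x, ...) {
  cat("Model parameter set (", x$scenario, " scenario, ", x$setting,
      " setting)\n", sep = "")
  cat("  start age ", x$start_age, ", max age ", x$max_age,
      ", cohort ", x$cohort_size, "\n", sep = "")
  cat("  annual failure: MR ", x$p_fail_mr_annual, ", PM ",
      x$p_fail_pm_annual, " (window ", x$failure_window_years,
      " cycles)\n", sep = "")
  cat("  OA after PM by period: ",
      paste(names(x$p_oa_pm_by_period), signif(x$p_oa_pm_by_period, 4),
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  RR of OA (MR vs PM): ", x$rr_oa_mr_vs_pm, " [", x$rr_mode,
      "]\n", sep = "")
  cat("  OA->TKR ", x$p_oa_to_tkr_annual, "; TKR revision by period: ",
      paste(names(x$p_tkr_revision_by_period),
            signif(x$p_tkr_revision_by_period, 4),
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  discounting ", 100 * x$discount_rate_costs, "% costs / ",
      100 * x$discount_rate_qalys, "% QALYs; WTP $",
      format(x$wtp_threshold, big.mark = ","), "/QALY\n", sep = "")
  invisible(x)
}

#' Export the parameter set as an audit table
#'
#' One row per scalar parameter with its base value and, where applicable,
#' the distribution family and sampling range used by the probabilistic
#' sensitivity analysis.
#'
#' @param params A `meniscus_params` object.
#' @param spec Optional [psa_spec()]; when supplied, the distribution family
#'   and 95% sampling interval are included.
#' @param file Optional path; when given, the table is written as CSV.
#' @return A data frame (invisibly when `file` is given).
#' @export
parameter_table <- function(params, spec = NULL, file = NULL) {
  flat <- .flatten_params(params)
  out <- data.frame(parameter = names(flat), base_value = unname(flat),
                    stringsAsFactors = FALSE)
  if (!is.null(spec)) {
    m <- match(out$parameter, spec$table$parameter)
    out$distribution <- ifelse(is.na(m), "fixed", spec$table$family[m])
    out$range_low <- spec$table$low[m]
    out$range_high <- spec$table$high[m]
  }
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}

# Flattens numeric parameters (expanding named vectors) for audit/PSA tables.
.flatten_params <- function(params) {
  out <- c()
  for (nm in names(params)) {
    v <- params[[nm]]
    if (!is.numeric(v)) next
    if (length(v) == 1) {
      out[nm] <- v
    } else {
      out[paste0(nm, ".", names(v))] <- v
    }
  }
  out
}
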