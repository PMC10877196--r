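# Incremental cost-effectiveness: dominance/ICER classification, net
# monetary benefit, acceptability curves, threshold searches and horizon
# sweeps, plus the top-level paired model run.

#' Compare two treatment arms
#'
#' Computes incremental cost, incremental QALYs, the ICER where defined, net
#' monetary benefit at the willingness-to-pay threshold, and the dominance
#' classification of the intervention against the comparator. Net monetary
#' benefit exactly zero is classified as not cost-effective (strict
#' inequality).
#'
#' @param intervention,comparator `arm_result` objects from [accumulate()]
#'   run under identical settings and horizons.
#' @param wtp Willingness-to-pay threshold in USD per QALY.
#' @return A `cea_result` with per-patient `delta_cost`, `delta_qalys`,
#'   `icer` (NA when incremental QALYs are zero), `nmb` and
#'   `classification` (one of `dominant`, `cost_effective`,
#'   `not_cost_effective`, `dominated`).
#' @export
compare_arms <- function(intervention, comparator, wtp = 100000) {
  if (!inherits(intervention, "arm_result") ||
      !inherits(comparator, "arm_result")) {
    stop("both arguments must be `arm_result` objects", call. = FALSE)
  }
  if (!identical(intervention$setting, comparator$setting) ||
      !identical(intervention$horizon, comparator$horizon) ||
      !identical(intervention$correction, comparator$correction) ||
      !identical(intervention$timing, comparator$timing)) {
    stop("arm results were produced under different settings/horizons",
         call. = FALSE)
  }
  dc <- intervention$cost_per_patient - comparator$cost_per_patient
  dq <- intervention$qalys_per_patient - comparator$qalys_per_patient
  icer <- if (dq != 0) dc / dq else NA_real_
  nmb <- wtp * dq - dc
  classification <- if (dc < 0 && dq > 0) {
    "dominant"
  } else if (dc > 0 && dq < 0) {
    "dominated"
  } else if (nmb > 0) {
    "cost_effective"
  } else {
    "not_cost_effective"
  }
  structure(list(delta_cost = dc, delta_qalys = dq, icer = icer, nmb = nmb,
                 wtp = wtp, classification = classification,
                 intervention = intervention$arm, comparator = comparator$arm,
                 setting = intervention$setting,
                 horizon = intervention$horizon),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Incremental result: ", x$intervention, " vs ", x$comparator, " (",
      x$setting, ", horizon ", x$horizon, ")\n", sep = "")
  cat("  per patient: dCost $", format(round(x$delta_cost), big.mark = ","),
      ", dQALYs ", round(x$delta_qalys, 3), "\n", sep = "")
  if (is.na(x$icer)) {
    cat("  ICER: undefined (dQALYs = 0)\n")
  } else {
    cat("  ICER: $", format(round(x$icer), big.mark = ","), "/QALY\n",
        sep = "")
  }
  cat("  NMB at $", format(x$wtp, big.mark = ",", scientific = FALSE), "/QALY: $",
      format(round(x$nmb), big.mark = ","), " -> ", x$classification, "\n",
      sep = "")
  invisible(x)
}

#' Run the paired cost-utility model
#'
#' The package's main entry point: projects both treatment arms (meniscal
#' repair and partial meniscectomy) under one parameter set and life table,
#' accumulates discounted costs and QALYs, and classifies the repair arm
#' against the meniscectomy arm at the willingness-to-pay threshold.
#'
#' @param params A `meniscus_params` object; defaults to the base case.
#' @param life_table A `life_table`; defaults to the built-in Gompertz table.
#' @param horizon_cycles Projection horizon in annual cycles (default:
#'   lifetime).
#' @param wtp Willingness-to-pay threshold (default: the parameter set's).
#' @return A `cea` object: list with `mr` and `pm` arm results, the traces,
#'   and the incremental `comparison`; has `print`, `summary`, `plot` and
#'   `simulate` methods (`simulate` runs the probabilistic sensitivity
#'   analysis).
#' @examples
#' fit <- run_cea()
#' fit
#' @export
run_cea <- function(params = build_parameter_set(),
                    life_table = synthetic_life_table(),
                    horizon_cycles = NULL, wtp = NULL) {
  if (is.null(wtp)) wtp <- params$wtp_threshold
  tr_mr <- run_cohort(params, life_table, "MR", horizon_cycles)
  tr_pm <- run_cohort(params, life_table, "PM", horizon_cycles)
  mr <- accumulate(tr_mr, params)
  pm <- accumulate(tr_pm, params)
  structure(list(mr = mr, pm = pm, trace_mr = tr_mr, trace_pm = tr_pm,
                 comparison = compare_arms(mr, pm, wtp),
                 params = params, life_table = life_table),
            class = "cea")
}

#' @export
print.cea <- function(x, ...) {
  cat("Cost-utility model run: MR vs PM, ", x$params$scenario, " scenario, ",
      x$params$setting, " setting, start age ", x$params$start_age, "\n",
      sep = "")
  print(x$comparison)
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  per1000 <- function(a) {
    scale <- 1000 / a$cohort_size
    c(revisions = unname(a$events["revisions"]) * scale,
      oa_cases = unname(a$events["oa_incidence"]) * scale,
      tkr = unname(a$events["tkr"]) * scale,
      rtkr = unname(a$events["rtkr"]) * scale,
      qalys = a$discounted_qalys * scale,
      cost = a$discounted_cost * scale)
  }
  tab <- rbind(PM = per1000(object$pm), MR = per1000(object$mr))
  tab <- rbind(tab, difference = tab["MR", ] - tab["PM", ])
  out <- list(table_per_1000 = tab, comparison = object$comparison,
              scenario = object$params$scenario,
              setting = object$params$setting,
              start_age = object$params$start_age)
  class(out) <- "summary.cea"
  out
}

#' @export
print.summary.cea <- function(x, ...) {
  cat("Lifetime results per 1,000 patients (", x$scenario, ", ", x$setting,
      ", start age ", x$start_age, ")\n", sep = "")
  print(round(x$table_per_1000, 1))
  cat("\n")
  print(x$comparison)
  invisible(x)
}

#' @export
plot.cea <- function(x, arm = c("MR", "PM"), ...) {
  arm <- match.arg(arm)
  tr <- if (arm == "MR") x$trace_mr else x$trace_pm
  occ <- .collapse_states(tr$occupancy)
  cycles <- 0:tr$horizon
  cols <- c("forestgreen", "darkolivegreen3", "orange", "red3", "purple",
            "brown", "grey40")
  graphics::matplot(cycles, occ, type = "l", lty = 1, col = cols,
                    xlab = "Cycle (years since index procedure)",
                    ylab = "Cohort occupancy",
                    main = paste0("State occupancy, ", arm, " arm"), ...)
  graphics::legend("right", legend = colnames(occ), col = cols, lty = 1,
                   cex = 0.8, bty = "n")
  invisible(x)
}

#' @rdname run_psa
#' @param object A `cea` object.
#' @param nsim Number of PSA iterations.
#' @param seed Root random seed.
#' @param ... Passed on to [psa_spec()].
#' @export
simulate.cea <- function(object, nsim = 10000, seed = 1, ...) {
  spec <- psa_spec(object$params, n_iterations = nsim, seed = seed, ...)
  run_psa(object$params, spec, object$life_table)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of draws whose net
#' monetary benefit `wtp * dQ - dC` is strictly positive.
#'
#' @param draws A data frame with columns `delta_cost` and `delta_qalys`
#'   (e.g. the `draws` element of a [run_psa()] result, or a `psa_result`
#'   itself).
#' @param wtp_grid Willingness-to-pay grid in USD/QALY (default $0-$150,000
#'   in $1,000 steps).
#' @return A `ceac` data frame with columns `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 150000, by = 1000)) {
  if (inherits(draws, "psa_result")) draws <- draws$draws
  if (!NROW(draws)) stop("`draws` is empty", call. = FALSE)
  if (!all(c("delta_cost", "delta_qalys") %in% names(draws))) {
    stop("`draws` needs columns delta_cost and delta_qalys", call. = FALSE)
  }
  frac <- vapply(wtp_grid, function(w) {
    mean(w * draws$delta_qalys - draws$delta_cost > 0)
  }, numeric(1))
  structure(data.frame(wtp = wtp_grid, prob_cost_effective = frac),
            class = c("ceac", "data.frame"))
}

#' @export
plot.ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$prob_cost_effective, type = "l", lwd = 2,
                 ylim = c(0, 1), xlab = "Willingness to pay ($/QALY)",
                 ylab = "Probability cost-effective",
                 main = "Cost-effectiveness acceptability curve", ...)
  invisible(x)
}

#' Bisection search for a decision-threshold parameter value
#'
#' Finds the value of a scalar model parameter at which the incremental
#' result crosses a decision boundary: `"dominance_boundary"` locates where
#' the incremental cost changes sign (cost-saving to cost-incurring), and
#' `"wtp_boundary"` locates where net monetary benefit at `wtp` changes sign
#' (cost-effective to not). Assumes the criterion is monotone in the
#' parameter across `bounds`.
#'
#' @param params Base `meniscus_params`.
#' @param life_table A `life_table`.
#' @param param_path Name of the scalar parameter to vary (e.g.
#'   `"rr_oa_mr_vs_pm"`).
#' @param bounds Length-2 numeric search interval.
#' @param criterion `"dominance_boundary"` or `"wtp_boundary"`.
#' @param wtp Willingness-to-pay threshold for the NMB criterion.
#' @param tol Bisection tolerance on the parameter (default 1e-3).
#' @param horizon_cycles Optional horizon (default lifetime).
#' @return The crossing value of the parameter.
#' @export
threshold_search <- function(params, life_table, param_path = "rr_oa_mr_vs_pm",
                             bounds, criterion = c("dominance_boundary",
                                                   "wtp_boundary"),
                             wtp = NULL, tol = 1e-3, horizon_cycles = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(wtp)) wtp <- params$wtp_threshold
  if (length(bounds) != 2 || bounds[1] >= bounds[2]) {
    stop("`bounds` must be an increasing length-2 interval", call. = FALSE)
  }
  objective <- function(value) {
    ov <- list(value); names(ov) <- param_path
    p <- build_parameter_set(utils::modifyList(unclass(params), ov))
    cmp <- run_cea(p, life_table, horizon_cycles, wtp)$comparison
    list(f = if (criterion == "dominance_boundary") cmp$delta_cost else
      -cmp$nmb, class = cmp$classification)
  }
  lo <- objective(bounds[1]); hi <- objective(bounds[2])
  if (sign(lo$f) == sign(hi$f)) {
    stop("criterion does not change sign over bounds: at ", bounds[1], " -> ",
         lo$class, ", at ", bounds[2], " -> ", hi$class, call. = FALSE)
  }
  a <- bounds[1]; b <- bounds[2]; fa <- lo$f
  while (b - a > tol) {
    m <- (a + b) / 2
    fm <- objective(m)$f
    if (fm == 0 || sign(fm) == sign(fa)) {
      a <- m; fa <- fm
    } else {
      b <- m
    }
  }
  (a + b) / 2
}

#' Incremental results across projection horizons
#'
#' Re-evaluates the incremental comparison truncated at every horizon from 1
#' to `max_horizon` cycles, using the same discounting and within-cycle
#' correction conventions. Both arms are projected once; accumulation is
#' truncated per horizon with no terminal-value extrapolation.
#'
#' @inheritParams threshold_search
#' @param max_horizon Longest horizon in cycles (default: lifetime).
#' @return A `horizon_sweep` data frame with one row per horizon: incremental
#'   cost and QALYs per patient, ICER, NMB and classification.
#' @export
horizon_sweep <- function(params, life_table, max_horizon = NULL, wtp = NULL) {
  if (is.null(wtp)) wtp <- params$wtp_threshold
  max_h <- params$max_age - params$start_age + 1
  if (is.null(max_horizon)) max_horizon <- max_h
  max_horizon <- min(max_horizon, max_h)
  tr_mr <- run_cohort(params, life_table, "MR", max_horizon)
  tr_pm <- run_cohort(params, life_table, "PM", max_horizon)
  rows <- lapply(seq_len(max_horizon), function(h) {
    cmp <- compare_arms(accumulate(tr_mr, params, horizon = h),
                        accumulate(tr_pm, params, horizon = h), wtp)
    data.frame(horizon = h, delta_cost = cmp$delta_cost,
               delta_qalys = cmp$delta_qalys, icer = cmp$icer,
               nmb = cmp$nmb, classification = cmp$classification,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("horizon_sweep", "data.frame"))
}
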