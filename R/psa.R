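# Parameter uncertainty: distribution assignment, reproducible draws, the
# probabilistic sensitivity analysis, and deterministic one-way analyses.

# Distribution assignment per parameter. Probabilities and utilities are
# Beta, costs Gamma, the relative risk and disutilities Log-normal. "+/-20%"
# ranges are read as 95% central intervals (sd = 0.2 * mean / 1.96);
# utilities use their published ranges as the 95% interval and draws are
# truncated to that range. Ages, discount rates, cycle length, the failure
# window and baseline mortality are not varied.
.psa_param_table <- function(params) {
  rel_sd <- function(m) 0.2 * m / 1.96
  rng_sd <- function(lo, hi) (hi - lo) / (2 * 1.96)
  row <- function(field, element, family, mean, sd, low = NA, high = NA,
                  truncate = FALSE) {
    data.frame(parameter = if (is.na(element)) field else
      paste0(field, ".", element),
      field = field, element = element, family = family,
      mean = mean, sd = sd, low = low, high = high,
      truncate = truncate, stringsAsFactors = FALSE)
  }
  rows <- list(
    row("p_fail_pm_annual", NA, "beta", params$p_fail_pm_annual,
        rel_sd(params$p_fail_pm_annual)),
    row("p_fail_mr_annual", NA, "beta", params$p_fail_mr_annual,
        rel_sd(params$p_fail_mr_annual)),
    row("p_oa_to_tkr_annual", NA, "beta", params$p_oa_to_tkr_annual,
        rel_sd(params$p_oa_to_tkr_annual)),
    row("p_procedure_mortality", NA, "beta", params$p_procedure_mortality,
        rel_sd(params$p_procedure_mortality)),
    row("rr_oa_mr_vs_pm", NA, "lnorm", params$rr_oa_mr_vs_pm,
        rel_sd(params$rr_oa_mr_vs_pm)),
    row("cost_tkr", NA, "gamma", params$cost_tkr, rel_sd(params$cost_tkr)),
    row("cost_rtkr", NA, "gamma", params$cost_rtkr, rel_sd(params$cost_rtkr)),
    row("cost_oa_state_annual", NA, "gamma", params$cost_oa_state_annual,
        rel_sd(params$cost_oa_state_annual))
  )
  for (el in names(params$p_oa_pm_by_period)) {
    m <- params$p_oa_pm_by_period[[el]]
    rows <- c(rows, list(row("p_oa_pm_by_period", el, "beta", m, rel_sd(m))))
  }
  for (el in names(params$p_tkr_revision_by_period)) {
    m <- params$p_tkr_revision_by_period[[el]]
    rows <- c(rows,
              list(row("p_tkr_revision_by_period", el, "beta", m, rel_sd(m))))
  }
  for (fld in c("cost_mr_index", "cost_pm_index_or_revision")) {
    for (el in names(params[[fld]])) {
      m <- params[[fld]][[el]]
      rows <- c(rows, list(row(fld, el, "gamma", m, rel_sd(m))))
    }
  }
  util_ranges <- list(u_no_oa = c(0.72, 1), u_oa = c(0.55, 0.83),
                      u_post_tkr = c(0.68, 1), u_post_rtkr = c(0.63, 0.94))
  for (fld in names(util_ranges)) {
    r <- util_ranges[[fld]]
    rows <- c(rows, list(row(fld, NA, "beta", params[[fld]],
                             rng_sd(r[1], r[2]), r[1], r[2],
                             truncate = TRUE)))
  }
  for (fld in c("disutil_meniscal_procedure", "disutil_tkr",
                "disutil_rtkr")) {
    rows <- c(rows, list(row(fld, NA, "lnorm", params[[fld]],
                             rel_sd(params[[fld]]))))
  }
  do.call(rbind, rows)
}

#' Specify the probabilistic sensitivity analysis
#'
#' Assigns a sampling distribution to every uncertain parameter by method of
#' moments: Beta for probabilities and utilities, Gamma for costs,
#' Log-normal for the relative risk and disutilities. Parameters whose
#' uncertainty is stated as "+/-20%" are given sd = 0.2 x mean / 1.96 (the
#' range read as a 95% central interval); utilities use their published
#' ranges the same way and their draws are truncated to the range.
#' Structural settings, ages, discount rates and baseline mortality are held
#' fixed.
#'
#' @param params Base `meniscus_params`.
#' @param n_iterations Number of PSA iterations (default 10,000).
#' @param seed Root seed; iteration `i` is drawn from its own stream whose
#'   seed is derived from `(seed, i)`, so iterations are order-independent
#'   and distinct root seeds give unrelated draw sets.
#' @param fixed Character vector of parameter names (rows of the
#'   distribution table) to hold at their base value, collapsing their
#'   distribution to a point mass.
#' @return A `psa_spec`: list with the distribution `table`, `n_iterations`
#'   and `seed`.
#' @export
psa_spec <- function(params, n_iterations = 10000, seed = 1,
                     fixed = character(0)) {
  if (seed < 0 || seed * 100003 + n_iterations >= 2^31) {
    stop("`seed` must be a non-negative integer below ", floor(2^31 / 100003),
         call. = FALSE)
  }
  tab <- .psa_param_table(params)
  unknown <- setdiff(fixed, c(tab$parameter, tab$field))
  if (length(unknown)) {
    stop("unknown parameter(s) in `fixed`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tab$family[tab$parameter %in% fixed | tab$field %in% fixed] <- "fixed"
  structure(list(table = tab, n_iterations = n_iterations, seed = seed),
            class = "psa_spec")
}

#' @export
print.psa_spec <- function(x, ...) {
  cat("PSA specification: ", x$n_iterations, " iterations, seed ", x$seed,
      "\n", sep = "")
  cat("  ", sum(x$table$family != "fixed"), " sampled parameters (",
      paste(names(table(x$table$family)), table(x$table$family),
            sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# Method-of-moments draws. Each returns a single value.
.draw_beta <- function(m, s) {
  v <- s^2
  if (v >= m * (1 - m)) stop("beta variance too large for mean ", m,
                             call. = FALSE)
  nu <- m * (1 - m) / v - 1
  stats::rbeta(1, m * nu, (1 - m) * nu)
}
.draw_gamma <- function(m, s) {
  if (m <= 0) stop("gamma mean must be positive", call. = FALSE)
  stats::rgamma(1, shape = (m / s)^2, rate = m / s^2)
}
.draw_lnorm <- function(m, s) {
  if (m <= 0) stop("log-normal mean must be positive", call. = FALSE)
  sdlog <- sqrt(log(1 + (s / m)^2))
  stats::rlnorm(1, log(m) - sdlog^2 / 2, sdlog)
}

.draw_one <- function(fam, m, s, low, high, truncate) {
  if (fam == "fixed") return(m)
  draw <- switch(fam,
    beta = function() .draw_beta(m, s),
    gamma = function() .draw_gamma(m, s),
    lnorm = function() .draw_lnorm(m, s)
  )
  x <- draw()
  if (isTRUE(truncate)) {
    tries <- 0
    while ((x < low || x > high) && tries < 1000) {
      x <- draw()
      tries <- tries + 1
    }
    x <- min(max(x, low), high)
  }
  x
}

# Write one flat value back into the parameter list.
.set_param <- function(params, field, element, value) {
  if (is.na(element)) {
    params[[field]] <- value
  } else {
    params[[field]][[element]] <- value
  }
  params
}

#' Draw one perturbed parameter set
#'
#' Reproducibly samples every uncertain parameter from its assigned
#' distribution for a given PSA iteration. The draw is a function of
#' `(spec$seed, draw_index)` only. A draw that fails parameter-set
#' validation is re-sampled from the continuing stream (with the re-sample
#' count attached as an attribute).
#'
#' @param base Base `meniscus_params`.
#' @param spec A [psa_spec()].
#' @param draw_index Iteration index (1-based).
#' @return A validated `meniscus_params` with attribute `resamples`.
#' @export
sample_psa <- function(base, spec, draw_index) {
  # per-iteration stream: disjoint across root seeds, order-independent
  set.seed(spec$seed * 100003 + draw_index)
  tab <- spec$table
  resamples <- 0
  repeat {
    p <- unclass(base)
    for (k in seq_len(nrow(tab))) {
      val <- .draw_one(tab$family[k], tab$mean[k], tab$sd[k], tab$low[k],
                       tab$high[k], tab$truncate[k])
      p <- .set_param(p, tab$field[k], tab$element[k], val)
    }
    out <- tryCatch(validate_parameter_set(p), error = function(e) NULL)
    if (!is.null(out)) break
    resamples <- resamples + 1
    if (resamples > 100) {
      stop("could not draw a valid parameter set after 100 attempts",
           call. = FALSE)
    }
  }
  attr(out, "resamples") <- resamples
  out
}

#' Probabilistic sensitivity analysis
#'
#' Runs the paired cohort model once per iteration under a common sampled
#' parameter set (the same draw drives both arms, so incremental uncertainty
#' reflects parameter uncertainty rather than independent arm noise) and
#' records per-patient incremental cost and QALYs.
#'
#' @param base Base `meniscus_params`.
#' @param spec A [psa_spec()].
#' @param life_table A `life_table` (held fixed across iterations).
#' @param wtp Willingness-to-pay used for the summary fraction.
#' @return A `psa_result`: list with `draws` (data frame `iteration`,
#'   `delta_cost`, `delta_qalys`), the fraction cost-effective at `wtp`, and
#'   metadata (seed, scenario, setting, re-sample count).
#' @examples
#' \donttest{
#' p <- build_parameter_set()
#' psa <- run_psa(p, psa_spec(p, n_iterations = 100, seed = 7),
#'                synthetic_life_table())
#' psa$fraction_cost_effective
#' }
#' @export
run_psa <- function(base, spec, life_table = synthetic_life_table(),
                    wtp = NULL) {
  if (is.null(wtp)) wtp <- base$wtp_threshold
  n <- spec$n_iterations
  dc <- numeric(n); dq <- numeric(n); resamples <- 0L
  for (i in seq_len(n)) {
    p <- sample_psa(base, spec, i)
    resamples <- resamples + attr(p, "resamples")
    tr_mr <- run_cohort(p, life_table, "MR")
    tr_pm <- run_cohort(p, life_table, "PM")
    mr <- accumulate(tr_mr, p)
    pm <- accumulate(tr_pm, p)
    dc[i] <- mr$cost_per_patient - pm$cost_per_patient
    dq[i] <- mr$qalys_per_patient - pm$qalys_per_patient
  }
  draws <- data.frame(iteration = seq_len(n), delta_cost = dc,
                      delta_qalys = dq)
  structure(list(
    draws = draws,
    fraction_cost_effective = mean(wtp * dq - dc > 0),
    wtp = wtp, seed = spec$seed, n_iterations = n,
    scenario = base$scenario, setting = base$setting,
    resamples = resamples
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("PSA: ", x$n_iterations, " iterations (seed ", x$seed, "), ",
      x$scenario, " scenario, ", x$setting, " setting\n", sep = "")
  cat("  cost-effective at $", format(x$wtp, big.mark = ",", scientific = FALSE), "/QALY: ",
      sprintf("%.2f%%", 100 * x$fraction_cost_effective), "\n", sep = "")
  cat("  mean dCost $", format(round(mean(x$draws$delta_cost)),
                               big.mark = ","),
      ", mean dQALYs ", round(mean(x$draws$delta_qalys), 3), "\n", sep = "")
  invisible(x)
}

#' @export
plot.psa_result <- function(x, ...) {
  graphics::plot(x$draws$delta_qalys, x$draws$delta_cost, pch = 16,
                 cex = 0.4, col = grDevices::adjustcolor("darkorange", 0.5),
                 xlab = "Incremental QALYs per patient",
                 ylab = "Incremental cost per patient ($)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::abline(a = 0, b = x$wtp, col = "red", lwd = 2)
  invisible(x)
}

#' Export PSA draws as CSV with a metadata sidecar
#'
#' @param psa A `psa_result`.
#' @param file CSV output path; the metadata JSON is written next to it with
#'   extension `.json`.
#' @return The draw table, invisibly.
#' @export
write_psa_csv <- function(psa, file) {
  utils::write.csv(psa$draws, file, row.names = FALSE)
  meta <- psa[c("seed", "n_iterations", "scenario", "setting", "wtp",
                "fraction_cost_effective", "resamples")]
  jsonlite::write_json(meta, sub("\\.csv$", ".json", file),
                       auto_unbox = TRUE, digits = NA)
  invisible(psa$draws)
}

#' Deterministic one-way sensitivity analysis
#'
#' Re-runs the full paired model at a low and a high value of one parameter,
#' all other inputs held at base.
#'
#' @param base Base `meniscus_params`.
#' @param life_table A `life_table`.
#' @param param_path Parameter name; elements of banded/by-setting vectors
#'   are addressed as `"field.element"` (e.g. `"p_oa_pm_by_period.1-5"`).
#' @param values List with components `low` and `high`.
#' @param wtp Willingness-to-pay threshold.
#' @return List with `low` and `high` `cea_result`s.
#' @export
one_way <- function(base, life_table, param_path, values, wtp = NULL) {
  if (is.null(wtp)) wtp <- base$wtp_threshold
  if (!all(c("low", "high") %in% names(values))) {
    stop("`values` must have components `low` and `high`", call. = FALSE)
  }
  parts <- strsplit(param_path, ".", fixed = TRUE)[[1]]
  field <- parts[1]
  element <- if (length(parts) > 1) {
    paste(parts[-1], collapse = ".")
  } else NA_character_
  if (!field %in% names(base)) {
    stop("unknown parameter: ", field, call. = FALSE)
  }
  run_at <- function(v) {
    p <- validate_parameter_set(.set_param(unclass(base), field, element, v))
    run_cea(p, life_table, wtp = wtp)$comparison
  }
  list(low = run_at(values$low), high = run_at(values$high))
}

#' One-way sweep over every sampled parameter
#'
#' Applies a symmetric relative perturbation (default +/-20%) to each
#' parameter the PSA samples, one at a time, and records the resulting
#' classification at both extremes. Utility upper values are capped at 1.
#'
#' @param base Base `meniscus_params`.
#' @param life_table A `life_table`.
#' @param rel Relative perturbation (default 0.2).
#' @param wtp Willingness-to-pay threshold.
#' @return Data frame: parameter, low/high value and classification at each.
#' @export
one_way_sweep <- function(base, life_table, rel = 0.2, wtp = NULL) {
  tab <- .psa_param_table(base)
  rows <- lapply(seq_len(nrow(tab)), function(k) {
    m <- tab$mean[k]
    lo <- m * (1 - rel)
    hi <- min(m * (1 + rel),
              if (grepl("^u_", tab$field[k])) 1 else Inf)
    res <- one_way(base, life_table, tab$parameter[k],
                   list(low = lo, high = hi), wtp)
    data.frame(parameter = tab$parameter[k], low = lo, high = hi,
               class_low = res$low$classification,
               class_high = res$high$classification,
               nmb_low = res$low$nmb, nmb_high = res$high$nmb,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
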