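# Cohort engine: per-cycle transition matrices, occupancy projection, event
# tallies, within-cycle correction, discounting, and cost/QALY accumulation.
#
# The reported model has 7 health states. Internally the no-OA and OA states
# are split by revision status (the repair-failure risk in the first cycles
# applies to every living patient who has not yet been revised, and revision
# status switches the osteoarthritis progression stream), and the post-TKR
# state is expanded into years-since-TKR sub-states so the banded TKR
# revision probabilities have the clock they need. Sub-states are collapsed
# back to the 7 reported states for output.

.INTERNAL_STATES <- c(
  "NoOA_postPrimary", "NoOA_postRevision", "OA_unrevised", "OA_revised",
  paste0("PostTKR_y", 1:10), "PostTKR_y11plus", "PostRTKR", "Death"
)
.N_STATES <- length(.INTERNAL_STATES)  # 17
.TKR_IDX <- 5:15
.DEATH_IDX <- 17L

#' Reported model states
#'
#' The seven health states of the reported model, in projection order. The
#' TKR state is the one-cycle tunnel in which the replacement takes place.
#'
#' @return Character vector of length 7.
#' @export
state_space <- function() {
  c("NoOA_postPrimary", "NoOA_postRevision", "OA", "TKR", "PostTKR",
    "PostRTKR", "Death")
}

# Map internal occupancy columns to the 7 reported states.
.collapse_states <- function(occ) {
  cbind(
    NoOA_postPrimary  = occ[, 1],
    NoOA_postRevision = occ[, 2],
    OA       = occ[, 3] + occ[, 4],
    TKR      = occ[, 5],
    PostTKR  = rowSums(occ[, 6:15, drop = FALSE]),
    PostRTKR = occ[, 16],
    Death    = occ[, 17]
  )
}

# Per-cycle transition inputs for one arm. Year bands are whole cycles since
# the origin event: the OA bands count cycles since primary treatment (the
# cycle index), the TKR revision bands count years since the TKR.
.cycle_probs <- function(params, life_table, cycle, arm) {
  age <- params$start_age + cycle - 1
  q <- q_at_age(life_table, age)
  f_arm <- if (arm == "MR") params$p_fail_mr_annual else params$p_fail_pm_annual
  f <- if (cycle <= params$failure_window_years) f_arm else 0
  band <- if (cycle <= 5) "1-5" else if (cycle <= 10) "6-10" else "11+"
  p_oa_pm <- unname(params$p_oa_pm_by_period[band])
  p_oa_arm <- if (arm == "MR") {
    rr_adjust_prob(p_oa_pm, params$rr_oa_mr_vs_pm, params$rr_mode)
  } else p_oa_pm
  # revision status switches progression to the comparator stream by default
  p_oa_rev <- if (params$post_revision_progression == "comparator") {
    p_oa_pm
  } else p_oa_arm
  rv <- params$p_tkr_revision_by_period
  r_y <- if (params$rtkr_clock == "since_tkr") {
    unname(c(rep(rv["1-4"], 4), rep(rv["5-9"], 5), rv["10"], rv["11+"]))
  } else {
    # clock runs from the primary treatment: one band per cycle index,
    # identical for every post-TKR year sub-state
    rband <- if (cycle <= 4) rv["1-4"] else if (cycle <= 9) rv["5-9"] else
      if (cycle == 10) rv["10"] else rv["11+"]
    rep(unname(rband), 11)
  }
  list(q = q, f = f, p_oa_u = p_oa_arm, p_oa_r = p_oa_rev,
       p_tkr = params$p_oa_to_tkr_annual, r_y = r_y,
       pm = params$p_procedure_mortality)
}

#' Build the transition probability matrix for one cycle
#'
#' Assembles the row-stochastic transition matrix over the internal
#' (expanded) state space for a given cycle and treatment arm. Baseline
#' mortality competes first in every row; surviving patients then face the
#' cycle's event probabilities, with the per-procedure mortality attached to
#' revision, TKR and revision-TKR events.
#'
#' @param params A `meniscus_params` object.
#' @param life_table A `life_table` covering the cohort's age at this cycle.
#' @param cycle Cycle index (1-based; cycle 1 spans the year after the index
#'   procedure).
#' @param arm `"MR"` or `"PM"`.
#' @return A 17 x 17 row-stochastic matrix over the internal states (the 7
#'   reported states with the OA/no-OA revision split and post-TKR year
#'   sub-states).
#' @export
build_transition_matrix <- function(params, life_table, cycle,
                                    arm = c("MR", "PM")) {
  arm <- match.arg(arm)
  cp <- .cycle_probs(params, life_table, cycle, arm)
  q <- cp$q; f <- cp$f; pm <- cp$pm
  M <- matrix(0, .N_STATES, .N_STATES,
              dimnames = list(.INTERNAL_STATES, .INTERNAL_STATES))

  # NoOA, unrevised: failure (revision resection), then OA among non-failed
  M[1, 17] <- q + (1 - q) * f * pm
  M[1, 2]  <- (1 - q) * f * (1 - pm)
  M[1, 3]  <- (1 - q) * (1 - f) * cp$p_oa_u
  M[1, 1]  <- (1 - q) * (1 - f) * (1 - cp$p_oa_u)

  # NoOA, revised: no further meniscal failure
  M[2, 17] <- q
  M[2, 4]  <- (1 - q) * cp$p_oa_r
  M[2, 2]  <- (1 - q) * (1 - cp$p_oa_r)

  # OA, unrevised: still at risk of repair failure during the window; all
  # surviving OA patients face the TKR probability
  surv_fail <- 1 - f * pm             # alive after the failure event resolves
  M[3, 17] <- q + (1 - q) * (f * pm + surv_fail * cp$p_tkr * pm)
  M[3, 5]  <- (1 - q) * surv_fail * cp$p_tkr * (1 - pm)
  M[3, 3]  <- (1 - q) * (1 - f) * (1 - cp$p_tkr)
  M[3, 4]  <- (1 - q) * f * (1 - pm) * (1 - cp$p_tkr)

  # OA, revised
  M[4, 17] <- q + (1 - q) * cp$p_tkr * pm
  M[4, 5]  <- (1 - q) * cp$p_tkr * (1 - pm)
  M[4, 4]  <- (1 - q) * (1 - cp$p_tkr)

  # Post-TKR year sub-states: banded revision risk, then age one year
  for (j in seq_along(.TKR_IDX)) {
    i <- .TKR_IDX[j]
    r <- cp$r_y[j]
    nxt <- if (i < 15L) i + 1L else 15L
    M[i, 17]  <- q + (1 - q) * r * pm
    M[i, 16]  <- (1 - q) * r * (1 - pm)
    M[i, nxt] <- M[i, nxt] + (1 - q) * (1 - r)
  }

  # Post revision-TKR: no further revision
  M[16, 17] <- q
  M[16, 16] <- 1 - q
  M[17, 17] <- 1

  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-12)) {
    stop("internal error: transition matrix rows do not sum to 1 (max |err| ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  M
}

#' Project a treatment arm's cohort through the model
#'
#' Runs the annual-cycle cohort projection for one arm from the all-in start
#' (everyone in the no-OA post-primary state at time zero, having undergone
#' the index procedure), recording state occupancy at every cycle boundary
#' and per-cycle event tallies (revision resections, incident OA, TKRs,
#' revision TKRs, deaths).
#'
#' @inheritParams build_transition_matrix
#' @param horizon_cycles Number of annual cycles to project; defaults to the
#'   lifetime horizon `max_age - start_age + 1` and is capped there.
#' @return A `cohort_trace`: list with `occupancy` (a `(horizon+1) x 17`
#'   matrix over internal states, row 1 = time zero), `events` (a
#'   `horizon x 5` matrix), plus the run metadata.
#' @examples
#' p <- build_parameter_set()
#' lt <- synthetic_life_table()
#' tr <- run_cohort(p, lt, arm = "MR")
#' colSums(tr$events)[c("revisions", "oa_incidence")]
#' @export
run_cohort <- function(params, life_table, arm = c("MR", "PM"),
                       horizon_cycles = NULL) {
  arm <- match.arg(arm)
  max_h <- params$max_age - params$start_age + 1
  if (is.null(horizon_cycles)) horizon_cycles <- max_h
  if (horizon_cycles < 1) stop("horizon_cycles must be >= 1", call. = FALSE)
  H <- min(horizon_cycles, max_h)

  n <- params$cohort_size
  occ <- matrix(0, H + 1, .N_STATES,
                dimnames = list(0:H, .INTERNAL_STATES))
  events <- matrix(0, H, 5, dimnames = list(
    1:H, c("revisions", "oa_incidence", "tkr", "rtkr", "deaths")))

  # the cohort enters the model having undergone the index procedure; the
  # per-procedure mortality attaches to subsequent revision/TKR/R-TKR events
  s <- numeric(.N_STATES)
  s[1] <- n
  occ[1, ] <- s

  for (t in seq_len(H)) {
    cp <- .cycle_probs(params, life_table, t, arm)
    q <- cp$q; f <- cp$f; pmort <- cp$pm
    s_new <- numeric(.N_STATES)

    a1 <- s[1] * (1 - q)                 # NoOA unrevised survivors
    fail1 <- a1 * f
    oa_n1 <- (a1 - fail1) * cp$p_oa_u
    s_new[1] <- a1 - fail1 - oa_n1

    a2 <- s[2] * (1 - q)
    oa_n2 <- a2 * cp$p_oa_r
    s_new[2] <- a2 - oa_n2 + fail1 * (1 - pmort)

    a3 <- s[3] * (1 - q)                 # OA unrevised survivors
    fail3 <- a3 * f
    pool_u <- a3 - fail3
    fail3_surv <- fail3 * (1 - pmort)
    a4 <- s[4] * (1 - q)
    tkr_cand <- pool_u + fail3_surv + a4
    tkr_ev <- tkr_cand * cp$p_tkr
    s_new[3] <- pool_u * (1 - cp$p_tkr) + oa_n1
    s_new[4] <- (fail3_surv + a4) * (1 - cp$p_tkr) + oa_n2
    s_new[5] <- tkr_ev * (1 - pmort)

    tkr_alive <- s[.TKR_IDX] * (1 - q)
    rev_y <- tkr_alive * cp$r_y
    stay <- tkr_alive - rev_y
    s_new[6:15] <- s_new[6:15] + stay[1:10]
    s_new[15] <- s_new[15] + stay[11]
    rtkr_ev <- sum(rev_y)
    s_new[16] <- s[16] * (1 - q) + rtkr_ev * (1 - pmort)

    deaths <- q * sum(s[-.DEATH_IDX]) +
      (fail1 + fail3 + tkr_ev + rtkr_ev) * pmort
    s_new[.DEATH_IDX] <- s[.DEATH_IDX] + deaths

    events[t, ] <- c(fail1 + fail3, oa_n1 + oa_n2, tkr_ev, rtkr_ev, deaths)
    s <- s_new
    occ[t + 1, ] <- s
  }

  structure(list(occupancy = occ, events = events, arm = arm,
                 horizon = H, params = params,
                 life_table_source = life_table$source),
            class = "cohort_trace")
}

#' Within-cycle correction of a cohort trace
#'
#' Converts boundary occupancies into effective per-cycle occupancy.
#' `"half_cycle"` prepends a half-duration cycle at model start so that state
#' membership is credited as if transitions occur mid-cycle; `"trapezoid"`
#' averages the start- and end-of-cycle occupancies; the two are numerically
#' equivalent for a cohort trace. `"none"` uses end-of-cycle occupancy.
#'
#' @param trace A `cohort_trace`.
#' @param method `"half_cycle"`, `"trapezoid"` or `"none"`.
#' @return A `horizon x 17` matrix of effective occupancy per cycle.
#' @export
within_cycle_correct <- function(trace,
                                 method = c("half_cycle", "trapezoid",
                                            "none")) {
  method <- match.arg(method)
  occ <- trace$occupancy
  H <- trace$horizon
  switch(method,
    half_cycle = {
      # half cycle at entry, then full credit at each boundary reached:
      # cycle t gets half of its entry occupancy plus half of its exit
      ext <- rbind(occ[1, ], occ)  # duplicated start row = the half cycle
      0.5 * ext[seq_len(H) + 1, , drop = FALSE] +
        0.5 * occ[seq_len(H) + 1, , drop = FALSE]
    },
    trapezoid = (occ[seq_len(H), , drop = FALSE] +
                   occ[seq_len(H) + 1, , drop = FALSE]) / 2,
    none = occ[seq_len(H) + 1, , drop = FALSE]
  )
}

#' Present value of a per-cycle stream
#'
#' Discounts a stream of per-cycle amounts at an annual rate. Under the
#' mid-cycle timing convention (used together with within-cycle correction)
#' cycle `t` is discounted by `(1+rate)^-(t-0.5)`; `"end"` uses `t`,
#' `"start"` uses `t-1`.
#'
#' @param values Numeric vector, one amount per cycle (cycle 1 first).
#' @param rate Annual discount rate (>= 0).
#' @param timing `"midcycle"`, `"end"` or `"start"`.
#' @return The present value (scalar).
#' @examples
#' discount_stream(rep(1, 10), 0.03, timing = "end")  # 10-year annuity factor
#' @export
discount_stream <- function(values, rate,
                            timing = c("midcycle", "end", "start")) {
  timing <- match.arg(timing)
  if (rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  if (!length(values)) return(0)
  offset <- switch(timing, midcycle = 0.5, end = 0, start = 1)
  t <- seq_along(values)
  sum(values / (1 + rate)^(t - offset))
}

#' Accumulate discounted costs and QALYs for one arm
#'
#' Applies within-cycle correction to the occupancy trace, weights state
#' occupancy by utilities and the annual OA-management cost (charged in the
#' OA, post-TKR and post-revision-TKR states), attaches per-event procedure
#' costs and disutilities, and discounts everything to present value. The
#' index procedure cost and disutility fall at time zero, undiscounted.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param params The `meniscus_params` the trace was run with.
#' @param correction Within-cycle correction method; defaults to the
#'   parameter set's choice.
#' @param timing Discount timing convention; defaults to the parameter set's
#'   choice.
#' @param horizon Optional shorter horizon (in cycles) over which to
#'   accumulate, for budget-window analyses; defaults to the full trace.
#' @return An `arm_result` with discounted cost and QALYs (total and per
#'   patient) and lifetime event totals.
#' @export
accumulate <- function(trace, params, correction = NULL, timing = NULL,
                       horizon = NULL) {
  if (is.null(correction)) correction <- params$within_cycle_correction
  if (is.null(timing)) timing <- params$discount_timing
  H <- if (is.null(horizon)) trace$horizon else min(horizon, trace$horizon)
  if (H < 1) stop("horizon must be >= 1", call. = FALSE)

  sub <- trace
  sub$occupancy <- trace$occupancy[seq_len(H + 1), , drop = FALSE]
  sub$horizon <- H
  occ_c <- within_cycle_correct(sub, method = correction)
  ev <- trace$events[seq_len(H), , drop = FALSE]
  pc <- .proc_costs(params)
  n <- params$cohort_size

  u_state <- c(params$u_no_oa, params$u_no_oa, params$u_oa, params$u_oa,
               rep(params$u_post_tkr, 11), params$u_post_rtkr, 0)
  qaly_cycle <- as.vector(occ_c %*% u_state)
  disutil_cycle <- ev[, "revisions"] * params$disutil_meniscal_procedure +
    ev[, "tkr"] * params$disutil_tkr + ev[, "rtkr"] * params$disutil_rtkr
  index_disutil <- n * params$disutil_meniscal_procedure

  qalys_disc <- discount_stream(qaly_cycle, params$discount_rate_qalys,
                                timing) -
    discount_stream(disutil_cycle, params$discount_rate_qalys, timing) -
    index_disutil
  qalys_undisc <- sum(qaly_cycle) - sum(disutil_cycle) - index_disutil

  state_cost_cycle <- pc$oa_annual *
    rowSums(occ_c[, 3:16, drop = FALSE])  # OA + post-TKR + post-R-TKR
  event_cost_cycle <- ev[, "revisions"] * pc$revision +
    ev[, "tkr"] * pc$tkr + ev[, "rtkr"] * pc$rtkr
  index_cost <- n * if (trace$arm == "MR") pc$mr_index else pc$pm_index
  cost_disc <- index_cost +
    discount_stream(state_cost_cycle + event_cost_cycle,
                    params$discount_rate_costs, timing)

  totals <- colSums(ev)
  structure(list(
    arm = trace$arm,
    setting = params$setting,
    horizon = H,
    discounted_cost = cost_disc,
    discounted_qalys = qalys_disc,
    undiscounted_qalys = qalys_undisc,
    cost_per_patient = cost_disc / n,
    qalys_per_patient = qalys_disc / n,
    events = totals,
    cohort_size = n,
    correction = correction,
    timing = timing
  ), class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(x$arm, " arm (", x$setting, ", horizon ", x$horizon, " cycles, cohort ",
      x$cohort_size, ")\n", sep = "")
  cat("  discounted cost : $", format(round(x$discounted_cost),
                                      big.mark = ","), "\n", sep = "")
  cat("  discounted QALYs: ", format(round(x$discounted_qalys, 1),
                                     big.mark = ","), "\n", sep = "")
  cat("  events: ", paste(names(x$events), round(x$events, 1), sep = "=",
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("Cohort trace: ", x$arm, " arm, ", x$horizon, " annual cycles, cohort ",
      x$params$cohort_size, "\n", sep = "")
  tot <- colSums(x$events)
  cat("  lifetime events: ",
      paste(names(tot), round(tot, 1), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  occ7 <- .collapse_states(x$occupancy)
  H <- x$horizon
  ev <- rbind(rep(0, ncol(x$events)), x$events)
  data.frame(cycle = 0:H, occ7, ev, check.names = FALSE)
}

#' Export a cohort trace as CSV
#'
#' Writes one row per cycle with occupancy of the 7 reported states plus the
#' per-cycle event tallies. Deterministic inputs give bit-identical files.
#'
#' @param trace A `cohort_trace`.
#' @param file Output path.
#' @return The written data frame, invisibly.
#' @export
write_trace_csv <- function(trace, file) {
  df <- as.data.frame(trace)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
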