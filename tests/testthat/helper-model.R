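# Shared fixtures and the independent individual-level simulation used as an
# oracle for the cohort engine.

lt_base <- synthetic_life_table()

# near-immortal flat table for closed-form checks that need mortality off
flat_life_table <- function(q = 1e-9, age_min = 35, age_max = 110) {
  meniscea:::validate_life_table(
    meniscea:::new_life_table(age_min:age_max, rep(q, age_max - age_min + 1),
                              source = "flat-test"))
}

# parameter set with all disease dynamics switched off (alive/dead only)
two_state_params <- function(...) {
  build_parameter_set(list(
    p_fail_pm_annual = 0, p_fail_mr_annual = 0,
    p_oa_pm_by_period = c("1-5" = 0, "6-10" = 0, "11+" = 0),
    p_oa_to_tkr_annual = 0, p_procedure_mortality = 0,
    u_no_oa = 1, disutil_meniscal_procedure = 0, ...))
}

# Individual-level Monte-Carlo simulation with the same transition rules as
# the cohort engine, written independently (per-person sampled pathways
# rather than expected-value bookkeeping). Returns lifetime event totals
# scaled per 1,000.
microsim_events <- function(params, life_table, arm, n_ind = 1e5,
                            seed = 101) {
  set.seed(seed)
  H <- params$max_age - params$start_age + 1
  # states: 1 noOA-unrev, 2 noOA-rev, 3 OA-unrev, 4 OA-rev, 5 postTKR,
  # 6 postRTKR, 0 dead
  state <- rep(1L, n_ind)
  tkr_year <- rep(0L, n_ind)   # years since TKR (0 = no TKR yet)
  ev <- c(revisions = 0, oa_incidence = 0, tkr = 0, rtkr = 0)
  rv <- params$p_tkr_revision_by_period
  for (t in seq_len(H)) {
    cp <- meniscea:::.cycle_probs(params, life_table, t, arm)
    alive <- state > 0L
    if (!any(alive)) break
    # baseline mortality
    die <- alive & (stats::runif(n_ind) < cp$q)
    state[die] <- 0L
    # repair failure among unrevised survivors (no-OA or OA)
    at_risk <- state %in% c(1L, 3L)
    fail <- at_risk & (stats::runif(n_ind) < cp$f)
    ev["revisions"] <- ev["revisions"] + sum(fail)
    pdie <- fail & (stats::runif(n_ind) < cp$pm)
    state[pdie] <- 0L
    # OA onset from the no-OA states, decided before revision status flips:
    # failure and onset are exclusive within a cycle, as in the cohort engine
    u <- stats::runif(n_ind)
    new_oa <- (state == 1L & !fail & u < cp$p_oa_u) |
      (state == 2L & u < cp$p_oa_r)
    flip <- fail & !pdie
    state[flip] <- state[flip] + 1L      # 1 -> 2, 3 -> 4
    ev["oa_incidence"] <- ev["oa_incidence"] + sum(new_oa)
    # TKR conversion from established OA (not the cycle of onset)
    oa_est <- state %in% c(3L, 4L) & !new_oa
    get_tkr <- oa_est & (stats::runif(n_ind) < cp$p_tkr)
    ev["tkr"] <- ev["tkr"] + sum(get_tkr)
    pdie2 <- get_tkr & (stats::runif(n_ind) < cp$pm)
    state[pdie2] <- 0L
    enter <- get_tkr & !pdie2
    state[enter] <- 5L
    state[new_oa] <- ifelse(state[new_oa] == 1L, 3L, 4L)
    # TKR revision among those with a replacement from an earlier cycle
    in_tkr <- state == 5L & tkr_year >= 1L
    r_prob <- if (params$rtkr_clock == "since_tkr") {
      y <- pmin(tkr_year, 11L)
      unname(c(rep(rv["1-4"], 4), rep(rv["5-9"], 5), rv["10"],
               rv["11+"])[pmax(y, 1L)])
    } else {
      unname(if (t <= 4) rv["1-4"] else if (t <= 9) rv["5-9"] else
        if (t == 10) rv["10"] else rv["11+"])
    }
    revise <- in_tkr & (stats::runif(n_ind) < r_prob)
    ev["rtkr"] <- ev["rtkr"] + sum(revise)
    pdie3 <- revise & (stats::runif(n_ind) < cp$pm)
    state[pdie3] <- 0L
    state[revise & !pdie3] <- 6L
    tkr_year[state == 5L] <- tkr_year[state == 5L] + 1L
    tkr_year[enter] <- 1L
  }
  ev * 1000 / n_ind
}
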