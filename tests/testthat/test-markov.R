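random_params <- function() {
  oa1 <- runif(1, 0.02, 0.3)
  build_parameter_set(list(
    p_fail_pm_annual = runif(1, 0, 0.1),
    p_fail_mr_annual = runif(1, 0, 0.3),
    p_oa_pm_by_period = c("1-5" = oa1, "6-10" = runif(1, 0.01, oa1),
                          "11+" = runif(1, 0.001, 0.05)),
    rr_oa_mr_vs_pm = runif(1, 0.3, 1.2),
    p_oa_to_tkr_annual = runif(1, 0.005, 0.1),
    p_procedure_mortality = runif(1, 0, 0.02),
    rr_mode = sample(c("rate", "multiplicative"), 1),
    rtkr_clock = sample(c("since_primary", "since_tkr"), 1),
    failure_window_years = sample(c(1, 3, Inf), 1)))
}

test_that("transition matrices are row-stochastic for random valid inputs", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_params()
    for (cyc in c(1, 3, 4, 8, 12, 40)) {
      for (arm in c("MR", "PM")) {
        M <- build_transition_matrix(p, lt_base, cyc, arm)
        expect_equal(unname(rowSums(M)), rep(1, nrow(M)), tolerance = 1e-12)
        expect_true(all(M >= 0))
      }
    }
  }
})

test_that("the cohort projection agrees with explicit matrix products", {
  set.seed(8)
  for (i in 1:5) {
    p <- random_params()
    tr <- run_cohort(p, lt_base, "MR", horizon_cycles = 25)
    s <- tr$occupancy[1, ]
    for (t in 1:25) {
      s <- as.vector(s %*% build_transition_matrix(p, lt_base, t, "MR"))
      expect_equal(unname(s), unname(tr$occupancy[t + 1, ]),
                   tolerance = 1e-9)
    }
  }
})

test_that("cohort occupancy is conserved and non-negative at every cycle", {
  set.seed(9)
  for (i in 1:10) {
    p <- random_params()
    for (arm in c("MR", "PM")) {
      tr <- run_cohort(p, lt_base, arm)
      expect_equal(unname(rowSums(tr$occupancy)),
                   rep(p$cohort_size, tr$horizon + 1), tolerance = 1e-8)
      expect_true(all(tr$occupancy >= -1e-12))
      expect_true(all(tr$events >= -1e-12))
    }
  }
})

test_that("repair failure stops when the risk window closes", {
  p <- build_parameter_set()
  M3 <- build_transition_matrix(p, lt_base, 3, "MR")
  M4 <- build_transition_matrix(p, lt_base, 4, "MR")
  expect_gt(M3["NoOA_postPrimary", "NoOA_postRevision"], 0)
  expect_equal(M4["NoOA_postPrimary", "NoOA_postRevision"], 0)
  expect_equal(M4["OA_unrevised", "OA_revised"], 0)

  p_inf <- build_parameter_set(failure_window_years = Inf)
  M40 <- build_transition_matrix(p_inf, lt_base, 40, "MR")
  expect_gt(M40["NoOA_postPrimary", "NoOA_postRevision"], 0)
})

test_that("the PM OA exit probability matches the published band value", {
  p <- build_parameter_set()
  q <- meniscea:::q_at_age(lt_base, 35 + 3 - 1)
  M <- build_transition_matrix(p, lt_base, 3, "PM")
  f <- p$p_fail_pm_annual
  # OA transition among survivors not failing this cycle
  expect_equal(M["NoOA_postPrimary", "OA_unrevised"] / ((1 - q) * (1 - f)),
               0.1127, tolerance = 1e-12)
  M12 <- build_transition_matrix(p, lt_base, 12, "PM")
  expect_equal(M12["NoOA_postPrimary", "OA_unrevised"] / (1 - meniscea:::q_at_age(lt_base, 46)),
               0.0089, tolerance = 1e-12)
})

test_that("with mortality off, cumulative revisions compound in closed form", {
  # TKR conversion off too: every unrevised patient stays at risk of failure
  lt0 <- flat_life_table()
  p <- build_parameter_set(p_procedure_mortality = 0,
                           p_oa_to_tkr_annual = 0)
  tr <- run_cohort(p, lt0, "MR")
  expect_equal(sum(tr$events[, "revisions"]),
               1000 * (1 - (1 - 0.0912)^3), tolerance = 1e-6)
  trp <- run_cohort(p, lt0, "PM")
  expect_equal(sum(trp$events[, "revisions"]),
               1000 * (1 - (1 - 0.002)^3), tolerance = 1e-6)
})

test_that("within-cycle correction credits mid-cycle membership", {
  # one person alive for exactly one cycle, then dead
  tr <- list(occupancy = rbind(c(1, rep(0, 15), 0), c(0, rep(0, 15), 1)),
             horizon = 1)
  class(tr) <- "cohort_trace"
  expect_equal(sum(within_cycle_correct(tr, "half_cycle")[, 1]), 0.5)
  expect_equal(sum(within_cycle_correct(tr, "trapezoid")[, 1]), 0.5)
  expect_equal(sum(within_cycle_correct(tr, "none")[, 1]), 0)

  # constant occupancy is unaffected by the correction
  trc <- list(occupancy = matrix(rep(c(1, rep(0, 16)), 11), nrow = 11,
                                 byrow = TRUE), horizon = 10)
  class(trc) <- "cohort_trace"
  expect_equal(within_cycle_correct(trc, "half_cycle"),
               within_cycle_correct(trc, "none"))
})

test_that("half-cycle and trapezoid corrections give identical lifetime QALYs", {
  p <- build_parameter_set()
  for (arm in c("MR", "PM")) {
    tr <- run_cohort(p, lt_base, arm)
    a_h <- accumulate(tr, p, correction = "half_cycle")
    a_t <- accumulate(tr, p, correction = "trapezoid")
    expect_equal(a_h$discounted_qalys, a_t$discounted_qalys,
                 tolerance = 1e-9)
    expect_equal(a_h$discounted_cost, a_t$discounted_cost, tolerance = 1e-9)
  }
})

test_that("discounting follows the closed forms", {
  expect_equal(discount_stream(c(5, 7, 11), 0, "end"), 23)
  expect_equal(discount_stream(103, 0.03, "end"), 100)
  expect_equal(discount_stream(rep(1, 10), 0.03, "end"),
               (1 - 1.03^-10) / 0.03, tolerance = 1e-12)
  expect_equal(discount_stream(c(1, 1), 0.03, "midcycle"),
               1.03^0.5 * (1.03^-1 + 1.03^-2), tolerance = 1e-12)
  expect_error(discount_stream(1, -0.1), "rate")
})

test_that("accumulation reduces to pure disutility when utilities are zero", {
  p <- build_parameter_set(list(u_no_oa = 0, u_oa = 0, u_post_tkr = 0,
                                u_post_rtkr = 0))
  tr <- run_cohort(p, lt_base, "MR")
  a <- accumulate(tr, p)
  ev <- tr$events
  t <- seq_len(nrow(ev))
  dis <- ev[, "revisions"] * p$disutil_meniscal_procedure +
    ev[, "tkr"] * p$disutil_tkr + ev[, "rtkr"] * p$disutil_rtkr
  expected <- -sum(dis / 1.03^(t - 0.5)) -
    1000 * p$disutil_meniscal_procedure
  expect_equal(a$discounted_qalys, expected, tolerance = 1e-9)
  expect_lt(a$discounted_qalys, 0)
})

test_that("discounted QALYs never exceed undiscounted QALYs", {
  p <- build_parameter_set()
  for (arm in c("MR", "PM")) {
    a <- accumulate(run_cohort(p, lt_base, arm), p)
    expect_lte(a$discounted_qalys, a$undiscounted_qalys)
  }
})

test_that("the two-state reduction matches the analytic life expectancy", {
  p <- two_state_params()
  tr <- run_cohort(p, lt_base, "PM")
  # end-of-cycle occupancy, end-of-cycle discounting: survival-curve sum
  a0 <- accumulate(tr, p, correction = "none", timing = "end")
  expect_equal(a0$discounted_qalys / 1000,
               life_expectancy(lt_base, 0.03, "end"), tolerance = 1e-9)
  au <- accumulate(tr, p, correction = "none", timing = "end", horizon = 76)
  expect_equal(au$undiscounted_qalys / 1000, life_expectancy(lt_base),
               tolerance = 1e-9)
})

test_that("raising the repair failure rate lowers QALYs and raises revisions", {
  rates <- c(0.02, 0.0912, 0.2, 0.35)
  res <- lapply(rates, function(r) {
    p <- build_parameter_set(p_fail_mr_annual = r)
    accumulate(run_cohort(p, lt_base, "MR"), p)
  })
  qalys <- vapply(res, function(a) a$discounted_qalys, numeric(1))
  revs <- vapply(res, function(a) unname(a$events["revisions"]), numeric(1))
  expect_true(all(diff(qalys) < 0))
  expect_true(all(diff(revs) > 0))
})

test_that("trace export is stable and collapses to the 7 reported states", {
  p <- build_parameter_set()
  tr <- run_cohort(p, lt_base, "MR")
  df <- as.data.frame(tr)
  expect_identical(names(df)[2:8], state_space())
  expect_equal(unname(rowSums(df[, 2:8])), rep(1000, tr$horizon + 1),
               tolerance = 1e-8)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, f1)
  write_trace_csv(run_cohort(p, lt_base, "MR"), f2)
  expect_identical(readLines(f1), readLines(f2))
})
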