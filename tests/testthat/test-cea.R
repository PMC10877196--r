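fake_arm <- function(arm, cost, qalys, setting = "hospital", horizon = 76) {
  structure(list(arm = arm, setting = setting, horizon = horizon,
                 discounted_cost = cost * 1000, discounted_qalys = qalys * 1000,
                 cost_per_patient = cost, qalys_per_patient = qalys,
                 cohort_size = 1000, correction = "half_cycle",
                 timing = "midcycle",
                 events = c(revisions = 0, oa_incidence = 0, tkr = 0,
                            rtkr = 0, deaths = 0)),
            class = "arm_result")
}

test_that("incremental comparison classifies the four quadrants and the WTP rule", {
  dom <- compare_arms(fake_arm("MR", 900, 10.5), fake_arm("PM", 1000, 10))
  expect_equal(dom$classification, "dominant")
  expect_equal(dom$delta_cost, -100)
  expect_equal(dom$delta_qalys, 0.5)

  ce <- compare_arms(fake_arm("MR", 2000, 10.5), fake_arm("PM", 1000, 10),
                     wtp = 100000)
  expect_equal(ce$classification, "cost_effective")
  expect_equal(ce$icer, 2000)

  nce <- compare_arms(fake_arm("MR", 1000 + 1000, 10.01),
                      fake_arm("PM", 1000, 10), wtp = 100000)
  # NMB exactly zero sits on the strict boundary: not cost-effective
  expect_equal(nce$icer, 100000, tolerance = 1e-9)
  expect_equal(nce$nmb, 0, tolerance = 1e-9)
  expect_equal(nce$classification, "not_cost_effective")

  dmt <- compare_arms(fake_arm("MR", 1100, 9.5), fake_arm("PM", 1000, 10))
  expect_equal(dmt$classification, "dominated")

  tie <- compare_arms(fake_arm("MR", 1000, 10), fake_arm("PM", 1000, 10))
  expect_true(is.na(tie$icer))
  expect_equal(tie$nmb, 0)
})

test_that("comparison refuses mismatched run conditions", {
  expect_error(compare_arms(fake_arm("MR", 1, 1, setting = "ASC"),
                            fake_arm("PM", 1, 1)), "different")
  expect_error(compare_arms(fake_arm("MR", 1, 1, horizon = 10),
                            fake_arm("PM", 1, 1)), "different")
})

test_that("classification is invariant to cohort size", {
  for (n in c(250, 1000, 5000)) {
    p <- build_parameter_set(cohort_size = n)
    fit <- run_cea(p, lt_base)
    expect_equal(fit$comparison$classification, "dominant")
    if (n == 1000) base_dc <- fit$comparison$delta_cost
  }
  p1 <- build_parameter_set(cohort_size = 1)
  expect_equal(run_cea(p1, lt_base)$comparison$delta_cost, base_dc,
               tolerance = 1e-9)
})

test_that("the acceptability curve follows the draw geometry", {
  all_dom <- data.frame(delta_cost = c(-10, -200), delta_qalys = c(0.1, 0.3))
  cc <- ceac(all_dom, wtp_grid = c(0, 50000, 100000))
  expect_equal(cc$prob_cost_effective, c(1, 1, 1))

  mixed <- data.frame(delta_cost = c(-100, 50, 200, -5),
                      delta_qalys = c(0.1, 0.1, -0.2, 0.05))
  cc0 <- ceac(mixed, wtp_grid = 0)
  expect_equal(cc0$prob_cost_effective, mean(mixed$delta_cost < 0))

  # monotone non-decreasing in WTP when every draw gains QALYs
  pos <- data.frame(delta_cost = rnorm(200, 0, 500),
                    delta_qalys = runif(200, 0.01, 0.3))
  ccp <- ceac(pos)
  expect_true(all(diff(ccp$prob_cost_effective) >= 0))

  expect_error(ceac(data.frame(delta_cost = numeric(0),
                               delta_qalys = numeric(0))), "empty")
})

test_that("threshold search brackets must straddle a crossing", {
  p <- build_parameter_set()
  expect_error(threshold_search(p, lt_base, bounds = c(0.55, 0.55)),
               "increasing")
  expect_error(threshold_search(p, lt_base, bounds = c(0.5, 0.6),
                                criterion = "dominance_boundary"),
               "change sign")
})

test_that("threshold search is independent of the starting bracket", {
  p <- build_parameter_set()
  a <- threshold_search(p, lt_base, bounds = c(0.55, 1.5),
                        criterion = "dominance_boundary")
  b <- threshold_search(p, lt_base, bounds = c(0.8, 1.2),
                        criterion = "dominance_boundary")
  expect_equal(a, b, tolerance = 2e-3)
  # crossing verifies: below saves money, above costs money
  lo <- run_cea(build_parameter_set(rr_oa_mr_vs_pm = a - 0.01), lt_base)
  hi <- run_cea(build_parameter_set(rr_oa_mr_vs_pm = a + 0.01), lt_base)
  expect_lt(lo$comparison$delta_cost, 0)
  expect_gt(hi$comparison$delta_cost, 0)
})

test_that("horizon sweep matches full-horizon accumulation at its endpoint", {
  p <- build_parameter_set()
  hs <- horizon_sweep(p, lt_base)
  expect_equal(nrow(hs), 76)
  full <- run_cea(p, lt_base)
  expect_equal(hs$delta_cost[76], full$comparison$delta_cost,
               tolerance = 1e-9)
  expect_equal(hs$delta_qalys[76], full$comparison$delta_qalys,
               tolerance = 1e-9)
  # longer horizons accumulate larger savings once OA costs diverge
  expect_true(all(diff(hs$delta_cost[5:76]) < 0))
})

test_that("the model-run object prints, summarises and simulates", {
  fit <- run_cea(build_parameter_set(), lt_base)
  expect_s3_class(fit, "cea")
  expect_output(print(fit), "dominant")
  s <- summary(fit)
  expect_equal(dim(s$table_per_1000), c(3, 6))
  psa <- simulate(fit, nsim = 5, seed = 42)
  expect_s3_class(psa, "psa_result")
  expect_equal(nrow(psa$draws), 5)
})
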