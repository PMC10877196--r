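test_that("endpoint-to-annual conversion reproduces the published inputs", {
  # 2-year failure rates and the published annual probabilities
  expect_equal(round(endpoint_to_annual_prob(0.174, 2), 4), 0.0912)
  expect_equal(round(endpoint_to_annual_prob(0.056, 2), 4), 0.0284)
  expect_equal(round(endpoint_to_annual_prob(0.004, 2), 4), 0.0020)
  expect_identical(endpoint_to_annual_prob(0, 5), 0)
})

test_that("endpoint conversion rejects out-of-domain inputs", {
  expect_error(endpoint_to_annual_prob(1, 2), "cumulative_prob")
  expect_error(endpoint_to_annual_prob(-0.1, 2), "cumulative_prob")
  expect_error(endpoint_to_annual_prob(0.2, 0.5), "horizon_years")
})

test_that("endpoint conversion inverts cumulative compounding and is monotone", {
  set.seed(42)
  for (i in 1:25) {
    p <- runif(1, 0, 0.95)
    h <- sample(1:30, 1)
    a <- endpoint_to_annual_prob(p, h)
    expect_equal(1 - (1 - a)^h, p, tolerance = 1e-12)
  }
  grid <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(endpoint_to_annual_prob(grid, 5)) > 0))
  expect_true(all(diff(endpoint_to_annual_prob(0.3, 1:20)) < 0))
})

test_that("relative-risk adjustment behaves on both scales", {
  expect_equal(rr_adjust_prob(0.1127, 0.55, "multiplicative"),
               0.1127 * 0.55, tolerance = 1e-12)
  expect_equal(rr_adjust_prob(0.1127, 0.55, "rate"),
               1 - (1 - 0.1127)^0.55, tolerance = 1e-12)
  expect_equal(rr_adjust_prob(0.1127, 1), 0.1127)
  expect_equal(rr_adjust_prob(0, 0.55), 0)
  expect_error(rr_adjust_prob(0.6, 2, "multiplicative"), "exceeds 1")
  expect_error(rr_adjust_prob(0.5, -1), "positive")
})

test_that("parameter sets carry the base-case inputs and apply overrides", {
  p <- build_parameter_set()
  expect_s3_class(p, "meniscus_params")
  expect_equal(p$p_fail_mr_annual, 0.0912)
  expect_equal(unname(p$cost_mr_index["hospital"]), 4996)
  expect_equal(unname(p$p_oa_pm_by_period), c(0.1127, 0.0351, 0.0089))
  expect_equal(p$rr_oa_mr_vs_pm, 0.55)

  pv <- build_parameter_set(scenario = "various_techniques")
  expect_equal(pv$p_fail_mr_annual, 0.0284)

  p60 <- build_parameter_set(start_age = 60)
  expect_equal(p60$start_age, 60)
  same <- setdiff(names(p), "start_age")
  expect_identical(unclass(p60)[same], unclass(p)[same])
})

test_that("unknown keys and invalid values are rejected with field names", {
  expect_error(build_parameter_set(list(not_a_param = 1)), "not_a_param")
  expect_error(build_parameter_set(u_oa = 1.4), "u_oa")
  expect_error(build_parameter_set(cost_tkr = -5), "cost_tkr")
  expect_error(build_parameter_set(scenario = "laser"), "scenario")
  expect_error(build_parameter_set(setting = "clinic"), "setting")
})

test_that("JSON and YAML configuration files round-trip", {
  cfg <- list(scenario = "various_techniques", setting = "ASC",
              start_age = 50)
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, fj, auto_unbox = TRUE)
  pj <- build_parameter_set(fj)
  expect_equal(pj$p_fail_mr_annual, 0.0284)
  expect_equal(pj$setting, "ASC")
  expect_equal(pj$start_age, 50)

  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, fy)
  py <- build_parameter_set(fy)
  expect_equal(unclass(py), unclass(pj))
})

test_that("the audit table lists every numeric input with its distribution", {
  p <- build_parameter_set()
  tab <- parameter_table(p, spec = psa_spec(p))
  expect_true(all(c("p_fail_mr_annual", "p_oa_pm_by_period.1-5",
                    "cost_mr_index.hospital", "u_no_oa") %in% tab$parameter))
  expect_equal(tab$base_value[tab$parameter == "cost_tkr"], 38916)
  expect_equal(tab$distribution[tab$parameter == "cost_tkr"], "gamma")
  # fixed structural inputs are never sampled
  expect_equal(tab$distribution[tab$parameter == "discount_rate_qalys"],
               "fixed")
  expect_equal(tab$distribution[tab$parameter == "start_age"], "fixed")
  f <- withr::local_tempfile(fileext = ".csv")
  parameter_table(p, file = f)
  expect_true(file.exists(f))
})

test_that("the packaged example configuration builds the base case", {
  f <- system.file("extdata", "example_config.json", package = "meniscea")
  p <- build_parameter_set(f)
  expect_equal(unclass(p)[names(unclass(p)) != "start_age"],
               unclass(build_parameter_set())[names(unclass(p)) != "start_age"])
  expect_equal(p$start_age, 35)
})
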