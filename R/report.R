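# Report generation: base-case tables, the full analysis bundle, and run
# manifests for reproducibility.

.pkg_version <- function() {
  as.character(utils::packageVersion("meniscea"))
}

# Manifest describing one deterministic run configuration.
run_manifest <- function(params, life_table, seed = NA, psa_n = NA) {
  lt_checksum <- sum(life_table$q * seq_along(life_table$q))
  list(
    scenario = params$scenario,
    setting = params$setting,
    start_age = params$start_age,
    horizon = params$max_age - params$start_age + 1,
    seed = seed,
    psa_iterations = psa_n,
    life_table_source = life_table$source,
    life_table_checksum = signif(lt_checksum, 12),
    package_version = .pkg_version(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Base-case report
#'
#' Runs the paired lifetime model for both costing perspectives and emits
#' the headline per-1,000-patient table: lifetime revisions, OA cases, TKRs
#' and revision TKRs, total discounted QALYs and costs per arm, differences,
#' and the decision rule. Optionally written as CSV + JSON with a manifest.
#'
#' @param config Overrides list or JSON/YAML path for
#'   [build_parameter_set()].
#' @param life_table A `life_table`; default the built-in Gompertz table.
#' @param out_dir Optional output directory; created if missing.
#' @param horizon_cycles Optional horizon (default lifetime).
#' @return List with `table` (per-1,000 results, one cost row per setting),
#'   `decision`, `fits` (the two `cea` objects) and `manifest`.
#' @export
run_base_case <- function(config = list(), life_table = synthetic_life_table(),
                          out_dir = NULL, horizon_cycles = NULL) {
  fits <- lapply(c(hospital = "hospital", ASC = "ASC"), function(s) {
    params <- build_parameter_set(config, setting = s)
    run_cea(params, life_table, horizon_cycles)
  })
  s_hosp <- summary(fits$hospital)$table_per_1000
  s_asc <- summary(fits$ASC)$table_per_1000

  tab <- data.frame(
    outcome = c("revisions", "oa_cases", "tkr", "rtkr", "qalys",
                "cost_hospital", "cost_asc"),
    PM = c(s_hosp["PM", c("revisions", "oa_cases", "tkr", "rtkr", "qalys")],
           s_hosp["PM", "cost"], s_asc["PM", "cost"]),
    MR = c(s_hosp["MR", c("revisions", "oa_cases", "tkr", "rtkr", "qalys")],
           s_hosp["MR", "cost"], s_asc["MR", "cost"]),
    row.names = NULL
  )
  tab$difference <- tab$MR - tab$PM
  decision <- vapply(fits, function(f) f$comparison$classification,
                     character(1))
  params <- fits$hospital$params
  out <- list(table = tab, decision = decision, fits = fits,
              manifest = run_manifest(params, life_table))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "base_case_per_1000.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(table = tab, decision = as.list(decision),
           manifest = out$manifest),
      file.path(out_dir, "base_case.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Full analysis bundle
#'
#' Orchestrates the complete set of analyses: lifetime base case in both
#' costing perspectives, starting-age sweep, the pooled-techniques
#' effectiveness scenario, the relative-risk threshold search, the
#' year-by-year horizon sweep, and the probabilistic sensitivity analysis
#' with its acceptability curve. Results are written under `out_dir` with a
#' manifest; deterministic stages are byte-stable given the same inputs.
#'
#' @inheritParams run_base_case
#' @param out_dir Output directory (required).
#' @param psa_n PSA iterations (default 10,000; set lower for quick runs).
#' @param seed Root seed for the PSA.
#' @param ages Starting ages for the age sweep.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_full_analysis <- function(config = list(),
                              life_table = synthetic_life_table(),
                              out_dir, psa_n = 10000, seed = 1,
                              ages = c(30, 40, 50, 60), quiet = FALSE) {
  if (missing(out_dir)) stop("`out_dir` is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
    say(sprintf("[%s] done in %.1fs", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }
  results <- list()

  results$base_case <- stage("base_case",
    run_base_case(config, life_table, out_dir = out_dir))
  params <- results$base_case$fits$hospital$params

  results$age_sweep <- stage("age_sweep", {
    rows <- lapply(ages, function(a) {
      lt_a <- if (a >= min(life_table$age)) life_table else
        synthetic_life_table(age_min = a)
      f <- run_cea(build_parameter_set(config, start_age = a,
                                       setting = "hospital"), lt_a)
      data.frame(start_age = a,
                 delta_cost = f$comparison$delta_cost,
                 delta_qalys = f$comparison$delta_qalys,
                 classification = f$comparison$classification,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    utils::write.csv(df, file.path(out_dir, "age_sweep.csv"),
                     row.names = FALSE)
    df
  })

  results$scenario_pooled <- stage("scenario_pooled", {
    f <- run_cea(build_parameter_set(config,
                                     scenario = "various_techniques",
                                     setting = "hospital"), life_table)
    f$comparison
  })

  results$rr_threshold <- stage("rr_threshold", {
    list(
      dominance = threshold_search(params, life_table, "rr_oa_mr_vs_pm",
                                   c(0.55, 1.5), "dominance_boundary"),
      wtp = threshold_search(params, life_table, "rr_oa_mr_vs_pm",
                             c(0.55, 1.5), "wtp_boundary")
    )
  })

  results$horizon_sweep <- stage("horizon_sweep", {
    hs <- lapply(c(hospital = "hospital", ASC = "ASC"), function(s) {
      p <- build_parameter_set(config, setting = s)
      df <- horizon_sweep(p, life_table)
      utils::write.csv(df,
                       file.path(out_dir, paste0("horizon_sweep_", s, ".csv")),
                       row.names = FALSE)
      df
    })
    hs
  })

  results$psa <- stage("psa", {
    psa <- run_psa(params, psa_spec(params, n_iterations = psa_n,
                                    seed = seed), life_table)
    write_psa_csv(psa, file.path(out_dir, "psa_draws.csv"))
    cc <- ceac(psa)
    utils::write.csv(cc, file.path(out_dir, "ceac.csv"), row.names = FALSE)
    list(psa = psa, ceac = cc)
  })

  manifest <- run_manifest(params, life_table, seed = seed, psa_n = psa_n)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("analysis bundle written to ", out_dir)
  invisible(results)
}
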