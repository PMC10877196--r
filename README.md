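# meniscea

A Markov cohort cost-utility model comparing **meniscal repair (MR)** with
**partial meniscectomy (PM)** for horizontal cleavage tears of the
meniscus, from a US payor perspective.

## The problem

Repairing a horizontal cleavage tear fails (and needs a secondary
meniscectomy) far more often than a meniscectomy does in the first years
after surgery. But a preserved meniscus protects the knee: repaired
patients progress to symptomatic osteoarthritis (OA) at a reduced relative
risk, and therefore need fewer total knee replacements (TKR) and revision
replacements (R-TKR) over a lifetime. Whether the up-front cost and failure
rate of repair are worth the avoided OA-management and replacement costs is
a health-economic question, and this package answers it the standard way:

* a 7-state annual-cycle Markov cohort model (no OA post-primary, no OA
  post-revision, OA, TKR, post-TKR, post-R-TKR, death) projected from age
  35 to age 110;
* repair/meniscectomy failure risk applied for the first 3 cycles; banded
  OA progression probabilities after meniscectomy, scaled in the repair arm
  by a relative risk RR = 0.55; OA-to-TKR conversion at 2.27%/year; banded
  R-TKR probabilities; baseline mortality from a life table plus 0.3%
  per-procedure mortality;
* costs (2021 USD, hospital or ambulatory-surgical-center prices) and
  utilities accumulated with half-cycle correction and 3% annual
  discounting into per-patient discounted cost *C* and QALYs *Q*;
* the comparison reported as incremental cost and QALYs, the ICER
  (dC/dQ), and net monetary benefit NMB = WTP * dQ - dC at a
  willingness-to-pay threshold of $100,000/QALY, with dominance
  classification;
* uncertainty handled by one-way sensitivity analyses, bisection threshold
  searches, year-by-year horizon sweeps, and a 10,000-iteration
  probabilistic sensitivity analysis (Beta/Gamma/Log-normal parameter
  distributions) summarised as a cost-effectiveness plane and acceptability
  curve.

Baseline mortality uses a built-in Gompertz life table anchored to the
published endpoints (0.21% at age 35, 52.29% at age 110);
`load_life_table()` accepts a real SSA table from CSV.

## Worked example

```r
library(meniscea)
fit <- run_cea()       # base case: all-suture repair, hospital prices, age 35
summary(fit)
```

```
Lifetime results per 1,000 patients (all_suture, hospital, start age 35)
           revisions oa_cases   tkr  rtkr   qalys      cost
PM               6.0    646.2 338.2  43.7 18767.7  52349641
MR             248.2    473.0 241.0  30.4 19360.7  39861283
difference     242.3   -173.1 -97.2 -13.3   592.9 -12488359

Incremental result: MR vs PM (hospital, horizon 76)
  per patient: dCost $-12,488, dQALYs 0.593
  ICER: $-21,062/QALY
  NMB at $100,000/QALY: $71,782 -> dominant
```

Reading this: repair produces about 242 more revision resections per 1,000
patients (almost all inside the 3-year failure window) but 173 fewer OA
cases, 97 fewer knee replacements and 13 fewer revision replacements over a
lifetime. Per patient it saves about $12,500 in discounted costs and gains
about 0.59 discounted QALYs, so repair *dominates* meniscectomy (cheaper
and more effective); the negative ICER is reported for completeness only.

Other entry points:

```r
run_cea(build_parameter_set(setting = "ASC"))                 # ASC prices
run_cea(build_parameter_set(scenario = "various_techniques")) # pooled MR failure rate
simulate(fit, nsim = 10000, seed = 1)                         # PSA; plot() gives the CE plane
threshold_search(build_parameter_set(), synthetic_life_table(),
                 "rr_oa_mr_vs_pm", c(0.55, 1.5), "dominance_boundary")
horizon_sweep(build_parameter_set(), synthetic_life_table(), 10)
run_full_analysis(out_dir = "out")   # every analysis + CSV/JSON bundle
```

Configuration can also come from flat JSON/YAML files
(`build_parameter_set("config.json")`); a command-line wrapper lives at
`inst/scripts/run_analysis.R`.

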