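---
title: "A Markov cohort cost-utility model of meniscal repair versus partial meniscectomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model of meniscal repair versus partial meniscectomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meniscea)
```

## The decision problem

Horizontal cleavage tears of the meniscus can be treated by repairing the
meniscus (MR) or by resecting the damaged portion (partial meniscectomy,
PM). Repair fails and needs a secondary resection more often in the first
years, but a preserved meniscus protects the joint, so repaired knees
progress to symptomatic osteoarthritis (OA) -- and from there to total knee
replacement (TKR) and possibly a revision replacement (R-TKR) -- at a lower
rate. The trade-off is economic as much as clinical: a repair costs more up
front and fails more, but each avoided OA case saves years of OA management
costs and each avoided TKR saves a large procedure cost.

`meniscea` projects this trade-off over a lifetime from a US payor
perspective with a discrete-time Markov cohort model, and expresses it as
incremental cost, incremental quality-adjusted life-years (QALYs), and a
cost-effectiveness classification against a willingness-to-pay (WTP)
threshold of \$100,000/QALY.

## Model structure

The reported model has seven health states: no OA after the primary
procedure, no OA after a revision resection, OA, TKR (a one-cycle tunnel in
which the replacement takes place), post-TKR, post-R-TKR, and death. Cycles
are annual. A cohort (1,000 patients by default) starts all-in the no-OA
post-primary state at age 35 having just undergone its index procedure.

Internally the engine expands this space to 17 states for two clocks the
flat space cannot carry:

* the no-OA and OA states are split by revision status, because the
  repair-failure risk applies to every living patient who has not yet been
  revised -- whether or not OA has set in -- and because a failed repair ends
  in a meniscectomy, after which the patient follows meniscectomy OA
  progression rates (`post_revision_progression = "comparator"`, the
  default; `"arm"` retains the primary arm's rates);
* the post-TKR state carries years-since-TKR sub-states so that banded
  revision probabilities can be keyed on either clock (below).

Sub-states are collapsed back to the seven reported states in every output.

Per cycle, each row of the transition matrix is composed as: baseline
mortality first, then event probabilities among survivors, with the 0.3%
per-procedure mortality attached multiplicatively to revision, TKR and
R-TKR events (`1 - (1-q)(1-p)` style composition keeps rows stochastic
without renormalisation). The matrix builder validates row sums to 1e-12 on
every call.

## Inputs and their defaults

All inputs live in one validated parameter set
(`build_parameter_set()`); every value can be overridden from R, JSON or
YAML. The key entries:

| parameter | default | units / note |
|---|---|---|
| `p_fail_mr_annual` | 0.0912 (all-suture) / 0.0284 (pooled techniques) | annual probability, from 2-year failure endpoints via `endpoint_to_annual_prob()` |
| `p_fail_pm_annual` | 0.002 | annual probability |
| `failure_window_years` | 3 | failures beyond 3 years are not attributed to the index procedure; `Inf` removes the window |
| `p_oa_pm_by_period` | 0.1127 / 0.0351 / 0.0089 | annual OA probability after PM for years 1-5, 6-10, 11+ since primary treatment |
| `rr_oa_mr_vs_pm` | 0.55 | relative risk of OA progression, MR vs PM |
| `p_oa_to_tkr_annual` | 0.0227 | annual conversion from OA to TKR |
| `p_tkr_revision_by_period` | 0.019 / 0.01 / 0.009 / 0.006 | annual R-TKR probability by year band |
| `p_procedure_mortality` | 0.003 | per procedure |
| costs | MR 4,996 / 3,494; PM 3,433 / 1,931 (hospital / ASC); TKR 38,916; R-TKR 46,698; OA state 3,486/yr | 2021 USD; the OA annual cost also accrues in the post-TKR and post-R-TKR states |
| utilities | 0.9 no OA, 0.69 OA, 0.835 post-TKR, 0.785 post-R-TKR | per cycle |
| disutilities | 0.0077 meniscal procedure, 0.025 TKR, 0.05 R-TKR | per event |
| discount rates | 3% costs and QALYs | per year |

## Baseline mortality

The only input not fully specified by published tables is the age-specific
mortality stream. Only its endpoints are known: an annual death probability
of 0.21% at age 35 and 52.29% at age 110 (Social Security Administration
period table). `synthetic_life_table()` closes that gap with a Gompertz
(log-linear in age) interpolation through the endpoints, the standard shape
for adult mortality; a piecewise-linear option exists for sensitivity, and
`load_life_table()` accepts a real SSA table from CSV for exact replication
work.

What the synthetic table emulates well: the anchor probabilities, strict
monotonicity, and a realistic implied life expectancy at 35 (about 42
years). What it cannot emulate: the exact vintage-specific curvature of the
SSA table, which deviates from log-linearity at very old ages. Quantities
dominated by the first decade of the model (revision counts, early-horizon
classifications, incremental costs) are insensitive to this; absolute
lifetime QALY levels are the most exposed. We verified by substituting a
piecewise table through realistic SSA anchor values that the incremental
results move by well under 1%, so the Gompertz choice is not a material
limitation for the comparisons the package reports.

## Accounting conventions

**Within-cycle correction.** State membership is credited as if transitions
occur mid-cycle, implemented by adding a half-duration cycle at model entry
(`"half_cycle"`); the trapezoid rule (averaging start- and end-of-cycle
occupancy) is implemented separately and the test suite checks the two agree
to 1e-9 on lifetime QALYs. `"none"` (end-of-cycle accounting) is available
for comparison. Event streams (procedures) are flows, not stocks, and are
tallied raw.

**Discounting.** Both costs and QALYs are discounted at 3% per year.
Consistent with mid-cycle correction, cycle *t* is discounted by
`1.03^-(t-0.5)` (`discount_timing = "midcycle"`); end-of-cycle timing is
available. The index procedure cost and disutility fall at time zero,
undiscounted.

**Index procedure mortality.** The cohort is defined as patients who
underwent the index procedure, so the per-procedure mortality is applied to
modelled downstream procedures (revision, TKR, R-TKR), not at time zero.
This is also what the published per-1,000 revision counts imply: the full
cohort is at risk of failure in cycle 1.

## Design choices that were genuinely open

* **Scale of the relative risk.** Whether RR = 0.55 multiplies the annual
  probability directly or acts on the hazard (`1-(1-p)^rr`) is not
  determined by the sources. Both are implemented (`rr_mode`); the hazard
  scale is the default because it reproduces the published lifetime OA case
  counts slightly better and is the scale on which a relative risk from a
  meta-analysis is naturally portable.
* **Clock for R-TKR bands.** The banded revision probabilities can be keyed
  on years since the primary treatment (`rtkr_clock = "since_primary"`, the
  default, matching the source description of the bands) or years since the
  TKR itself (`"since_tkr"`, clinically the more natural clock). The
  difference is confined to R-TKR counts (tens per 1,000) and moves the
  incremental results by well under \$200 per patient.
* **Progression after a failed repair.** A failed repair ends in a
  meniscectomy, so by default the patient subsequently follows
  meniscectomy-rate OA progression. Keeping the repair-arm rates after
  revision is available behind a flag; it widens the incremental QALY gap by
  roughly a quarter and is hard to defend clinically.
* **Boundary classification.** Net monetary benefit exactly zero is
  classified as *not* cost-effective (strict inequality) -- conservative,
  and consequential only on measure-zero boundaries.
* **OA band clock.** OA progression bands count years since the primary
  treatment for everyone; a revision does not restart the OA clock.

## Parameter uncertainty

`psa_spec()` assigns each uncertain parameter a distribution by method of
moments: Beta for probabilities and utilities, Gamma for costs, Log-normal
for the relative risk and the disutility magnitudes. A "+/-20%" uncertainty
statement is read as a 95% central interval, giving `sd = 0.2 * mean /
1.96`; utilities instead use their published ranges as the 95% interval and
their draws are truncated to the range (so, e.g., the no-OA utility never
leaves [0.72, 1]). Ages, discount rates, the cycle length, the failure
window and baseline mortality are never sampled.

Each PSA iteration draws one parameter set and runs *both* arms with it, so
the spread of incremental results reflects decision uncertainty rather than
independent arm noise; the two arm-specific failure probabilities have
their own independent Beta draws within the common set. Iterations are
seeded individually from `root seed + iteration`, making the stream
order-independent and the whole analysis reproducible from one integer. An
invalid draw (possible in principle with heavy-tailed Log-normal values) is
re-sampled and counted.

The one-way machinery (`one_way()`, `one_way_sweep()`) re-runs the full
deterministic model at perturbed values of single parameters;
`threshold_search()` bisects a scalar parameter (tolerance 1e-3) to the
point where the incremental cost changes sign (dominance boundary) or net
monetary benefit changes sign at the WTP threshold; `horizon_sweep()`
truncates accumulation at every horizon from 1 cycle upward with no
terminal-value extrapolation, matching a payor's budget-window reading.

## Problem sizes and runtime

The deterministic engine is a 76-cycle projection over 17 internal states
and runs in a few milliseconds, so the lifetime base case, age sweeps,
horizon sweeps and bisection searches are all interactive. The default PSA
uses 10,000 iterations (about a minute on one CPU); the test suite checks
reproducibility at smaller sizes and the individual-level validation runs
100,000 simulated patients against the cohort expectation.

## Known limitations

* Absolute (per-arm) lifetime QALY and cost levels depend on the mortality
  stream and the accrual conventions above more than the incremental
  results do; the package's headline outputs are the increments.
* The published analysis this model parameterises reports QALY totals that
  are not jointly consistent with its printed utility values: over any
  plausible mortality stream, its per-patient QALYs imply an average
  utility below the OA state utility. The package reproduces incremental
  costs, event counts and classifications from the printed inputs, and
  documents that the printed QALY *totals* (and quantities downstream of
  them, such as the incremental QALY gain and the relative-risk decision
  thresholds) correspond instead to utilities near the lower ends of their
  published ranges. Users wanting that behaviour can simply set the four
  utilities to those values.
* No more than one meniscal revision and one TKR revision per patient; no
  separate medial/lateral stratification; one mortality stream for both
  sexes; no societal costs.
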