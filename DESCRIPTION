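Package: meniscea
Title: Markov Cohort Cost-Utility Model of Meniscal Repair Versus Partial
    Meniscectomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a seven-state annual-cycle Markov cohort model
    comparing all-suture meniscal repair with partial meniscectomy for
    horizontal cleavage tears of the meniscus, from a United States payor
    perspective. Projects lifetime revisions, osteoarthritis cases, total
    knee replacements and revision knee replacements, accumulates
    discounted costs and quality-adjusted life-years with within-cycle
    correction, and classifies cost-effectiveness against a
    willingness-to-pay threshold. Includes deterministic one-way and
    threshold sensitivity analyses, time-horizon sweeps, probabilistic
    sensitivity analysis with beta, gamma and log-normal parameter
    distributions, and cost-effectiveness acceptability curves. Baseline
    mortality comes from a user-supplied life table or a built-in Gompertz
    interpolation anchored to published endpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
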