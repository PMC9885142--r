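Package: navicer
Title: Cost-Effectiveness of Navigated Intramedullary Nailing for
    Intertrochanteric Hip Fracture
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Markov cohort decision model comparing computer-navigated
    intramedullary nailing (IMN) with traditional freehand IMN for
    intertrochanteric hip fractures in elderly patients. Implements the
    four-state annual-cycle cohort engine with discounted cost and
    quality-adjusted life-year (QALY) accounting, incremental
    cost-effectiveness ratios (ICER) and net monetary benefit, volume
    dependent allocation of the navigation-system cost, deterministic
    one-way and two-way sensitivity analyses, threshold (bisection)
    searches, probabilistic sensitivity analysis with Beta/Gamma
    parameter distributions, cost-effectiveness acceptability curves, a
    microsimulation verification oracle, and a calibration stage that
    resolves unstated cycle conventions and background mortality against
    reference-case outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
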