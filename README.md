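# navicer

Cost-effectiveness analysis of **computer-navigated intramedullary
nailing (IMN)** versus traditional freehand IMN for intertrochanteric
hip fractures, as a Markov cohort decision model in R.

Navigation systems place the lag screw inside the tip–apex-distance
safe zone (TAD < 20 mm) in ~95.6% of cases versus ~74.0% freehand,
roughly tripling the odds of avoiding fixation failure and the salvage
total hip arthroplasty (THA) it entails — but a system costs millions of
CNY to purchase and maintain. The package answers, from a payer
perspective in 2020 CNY for a 70-year-old reference patient: *at what
annual surgical volume, device price, or placement accuracy does
navigation become cost-effective?*

It is aimed at health-economics and orthopaedics researchers who want
the full analysis pipeline — reference case, deterministic and
probabilistic sensitivity analyses, threshold searches — reproducible,
configurable, and testable without any external data.

## The model

A four-state Markov cohort (annual cycles, 5-year horizon, 3% discount):
safe fixation, unsafe fixation, salvage THA, death. Perioperative
mortality 6%, first-postoperative-year mortality 20%, then age-specific
background mortality; annual failure 2.7% inside / 7.5% outside the safe
zone (the outside rate derived via the odds-ratio conversion
`p₁ = OR·p₀ / (1 − p₀ + OR·p₀)` with OR = 2.94); utilities 0.82 / 0.79 /
0.6 per year (navigated / traditional / THA, from a linear Harris Hip
Score mapping) with a one-time −0.15 disutility at salvage. Strategies
are compared by the incremental cost-effectiveness ratio
ICER = ΔCost/ΔQALY against a willingness-to-pay threshold of
¥140,000/QALY, and by net monetary benefit NMB = WTP·ΔQALY − ΔCost.
The navigation system cost enters per patient as
`(purchase/amortization + 5%·purchase) / annual volume`, so the ICER
falls with volume along an exact `A + B/V` curve.

Cycle-accounting conventions and the unpublished background-mortality
level are *calibrated* against the published reference-case anchors
(3.32 / 3.18 QALYs, ¥74,963 navigated cost) rather than guessed; every
other published quantity is then recomputed as an independent check.
See the methods vignette (`vignettes/navigated-imn-cea.Rmd`) for the
full account, including two documented discrepancies internal to the
published results.

## Worked example

```r
library(navicer)

p  <- default_parameters()      # calibrated defaults, volume 200/year
rc <- reference_case(p)
rc$navigated
#> navigated IMN: 3.32 QALYs, cost 74,963, salvage incidence 8.6%
rc$traditional
#> traditional IMN: 3.18 QALYs, cost 64,326, salvage incidence 11.2%
rc$cea
#> navigated vs traditional
#>   cost: 74,963 vs 64,326 (delta 10,637)
#>   QALY: 3.319 vs 3.181 (delta 0.1380)
#>   ICER: 77,094 per QALY
#>   salvage reduction: 23.8%
#>   NMB at WTP 140,000: 8,679; cost-effective: TRUE
```

At 200 navigated cases per year the navigated strategy gains 0.138
QALYs per patient for ¥10,637 extra — ¥77,094 per QALY, under the
¥140,000 threshold, while avoiding roughly a quarter of salvage
arthroplasties. The volume dependence and the break-even volume:

```r
round(icer_vs_volume(p, c(100, 200, 300))$icers, 1)
#> [1] 174744.2  77094.0  44544.0
threshold_search(p, "annual_volume", bracket = c(50, 300))
#> threshold on annual_volume (volume 200): > 121.64 (ICER there 140,000)
```

A low-volume institute (100 cases/year) pays ¥174,744 per QALY — not
cost-effective — and no achievable placement accuracy rescues it
(`threshold_search(p, "p_safe_nav", volume = 100, bracket = c(0.74, 0.9999))`
returns the no-solution sentinel); the crossing sits near 122 cases per
year. `run_psa()` and `ceac()` add parameter uncertainty;
`one_way_dsa()`, `two_way_dsa()` and `tornado_summary()` cover the
deterministic sensitivity analyses. A command-line wrapper is installed
at `inst/cli/navicer` (`navicer report --volume 200 --out results/`).

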