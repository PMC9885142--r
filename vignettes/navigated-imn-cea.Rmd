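---
title: "A Markov cohort model for the cost-effectiveness of navigated intramedullary nailing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for the cost-effectiveness of navigated intramedullary nailing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navicer)
```

## The decision problem

Intertrochanteric hip fractures in the elderly are usually fixed with an
intramedullary nail (IMN).  Fixation failure is strongly associated with
lag-screw position, summarized by the tip–apex distance (TAD): screws
placed with TAD < 20 mm (the "safe zone") fail at roughly 2.7% per year,
those outside at roughly 7.5% per year — the outside-zone rate is derived
from the inside-zone baseline via an odds ratio of 2.94 applied in odds
space (`or_to_probability()`).  Optical navigation systems place the screw
in the safe zone far more reliably (95.6% vs 74.0% of cases) and are
associated with better functional outcomes, but cost millions of CNY to
purchase and maintain.  The question the package answers: *for a
70-year-old patient, from a payer perspective in 2020 CNY, when does the
navigated procedure justify its cost?* — as a function of the annual
surgical volume over which the device cost is spread.

## Model structure

A four-state Markov cohort with annual cycles over a 5-year horizon:

1. **SAFE_FIX** — successful fixation, screw inside the safe zone;
2. **UNSAFE_FIX** — successful fixation, screw outside the safe zone;
3. **SALVAGE_THA** — salvage total hip arthroplasty after fixation
   failure (assumed never to fail again within the horizon);
4. **DEAD** — absorbing.

Entry: 6% perioperative mortality, survivors split by the arm's
safe-zone probability.  Each cycle applies, in order: background death
(a 20% mortality in the first postoperative year for fixation states,
the age-specific life-table rate afterwards and for the salvage state);
fixation failure at the zone-specific rate, with a 6% perioperative
mortality for the salvage THA, its cost, and a one-time −0.15 QALY
disutility for survivors entering the salvage state; and utility accrual
(0.82/0.79 per year for navigated/traditional fixation states regardless
of zone, 0.6 in the salvage state).  Costs and QALYs are discounted at
3% per year.  Both arms share all mortality and failure parameters; they
differ only in the safe-zone probability, the annual utility, and the
navigation cost.

```{r structure}
p <- default_parameters()
initial_distribution("navigated", p)
run_cohort("traditional", p)$trace[, c("cycle", "safe", "unsafe",
                                       "salvage", "dead", "cum_salvage")]
```

### What "salvage rate" means here

The reported `salvage_rate` is the cumulative incidence of *entering*
the salvage state — patients who survive the salvage THA and live in
that state.  The cumulative fraction *undergoing* the operation
(including its perioperative deaths) is reported separately as
`salvage_operations`; THA costs accrue per operation.  The entry-based
definition is what the published "state rate for salvage procedures"
matches.

## Cycle conventions and why they are calibrated

Discrete-time cohort software leaves several accounting choices
implicit, and the source publication does not state them.  They change
results materially, so the package represents them explicitly
(`model_conventions()`) and *calibrates* them instead of guessing:

* `initial_utility_accrual` — whether the entry state earns one cycle's
  utility at model entry (stage-boundary rewards, i.e. horizon + 1
  accruals).  Without it, the printed cumulative QALYs (3.32/3.18) are
  unattainable under the stated mortality: five accruals after 6%
  perioperative plus 20% first-year mortality cannot exceed about 3.0
  discounted QALYs.
* `dying_cycle_utility_fraction` — utility credited to patients dying
  within a cycle.  Fixed at 0.5 (deaths occur mid-cycle on average, the
  standard treatment) rather than calibrated: the rounded QALY anchors
  cannot distinguish 0 from 0.5, but the mid-cycle value is the one
  whose salvage incidences also agree with the published reference case,
  and it is the defensible convention independent of that agreement.
* `first_year_mortality_includes_periop` — whether the 20% first-year
  mortality already contains the 6% perioperative deaths.
* `discount_cycle_zero` — whether cycle-zero outlays (surgery, the
  initial accrual) are discounted one period.
* Background mortality — the cited census life table is not reproduced
  in the source, so a flat annual rate `q` stands in for it and is
  calibrated jointly.

`calibrate_conventions()` grids the three boolean conventions against
`q ∈ [0.005, 0.25]` (coarse step 0.001, then golden-section refinement)
and minimizes the summed squared relative error against exactly two
anchors: the published navigated (3.32) and traditional (3.18) QALYs.
`calibrate_amortization()` then backs the per-patient navigation cost
out of the third anchor, the navigated total cost (¥74,963), and inverts
the cost-allocation formula for the amortization period.  Everything
else the publication prints — the traditional arm's cost, both salvage
incidences, the salvage reduction, the ICERs at all three volumes, the
threshold table, the PSA summaries — is recomputed by the package and
compared as an *independent* check (see `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`).

```{r calibration, eval = FALSE}
cal <- calibrate_model()   # a few seconds; deterministic
cal
```

The shipped defaults (`calibrated_constants()`) are the frozen output of
that procedure: no initial-mortality double-counting
(`first_year_mortality_includes_periop = FALSE`), initial accrual on,
cycle-zero discounting on, and a flat background mortality of
`q ≈ 0.062`/year.  That rate is higher than census mortality for ages
71–75 (roughly 0.02–0.04): it absorbs the residual excess mortality that
elderly hip-fracture cohorts carry beyond the general population after
the first year, which the source model folded into its unpublished
life-table treatment.  A user-supplied life table (`life_table` entry in
the configuration, CSV with header `age,qx`) bypasses the flat stand-in
entirely.

The calibration is self-consistent by construction and by test: anchors
generated from any known convention/q combination are recovered exactly
(discrete part) and to 1e-4 in `q`.  If no configuration fits both QALY
anchors within 2%, `calibrate_model()` raises a calibration-failure
report rather than accepting the best bad fit.

## The navigation cost and the volume effect

The per-patient navigation cost is

```
(purchase / amortization_years + 0.05 * purchase) / annual_volume
```

— straight-line amortization plus maintenance at 5% of the purchase
price, spread over the institution's annual volume (the publication
states only that purchase and maintenance were "integrated into the
model", so the allocation formula is the package's, with the
amortization period calibrated; the calibrated value, about 2.9 years,
is reported rather than hidden).  Because only this term depends on the
volume V, the ICER follows `A + B/V` exactly; `icer_vs_volume()`
computes A and B analytically from one cohort run per arm, and the
structural identity `(ICER₁₀₀ − ICER₂₀₀)/(ICER₂₀₀ − ICER₃₀₀) = 3` holds
to numerical precision.

```{r volume}
icer_vs_volume(p, c(100, 200, 300))$icers
threshold_search(p, "annual_volume", bracket = c(50, 300))
```

## Deterministic sensitivity analyses

`one_way_dsa()` sweeps one parameter (default ±10% of its base value —
the publication prints no ranges, and ±10% mirrors the "sd = 10% of the
mean" rule its PSA table uses), classifying the ICER relationship as
positive, negative, or flat when the relative ICER span across the
range stays under 2%.  Two couplings matter:

* sweeping `cost_imn` moves `cost_tha = 2 × cost_imn` with it, because
  the salvage cost is defined as twice the primary procedure's; without
  the tie the IMN cost is paid identically by both arms and cancels from
  the ICER exactly;
* sweeping the perioperative mortality moves the THA perioperative
  mortality with it (both are the same published 6%).  Its ICER effect
  is near-zero because it scales both arms' costs and QALYs almost
  proportionally — the model's counterpart of the publication calling it
  inconsequential.

`two_way_dsa()` maps the navigation purchase price against the navigated
safe-zone probability at fixed volume, classifying each cell by the
net-monetary-benefit rule; the cost-effectiveness boundary is monotone
in both axes.  `threshold_search()` solves for parameter values where
ICER = WTP by bisection *on the net monetary benefit* (the ICER itself
has a pole where ΔQALY crosses zero inside natural brackets for the
utility and safe-zone parameters; the NMB is monotone there), verifies
monotonicity on a 17-point grid first, stops at |ICER − WTP| < ¥1/QALY
or a bracket below 1e-6 of its width, and returns an explicit
no-solution sentinel when even the favourable bracket end is not
cost-effective — which is exactly what happens for the safe-zone
probability at 100 cases/year.

## Probabilistic sensitivity analysis

`run_psa()` draws the nine distributed parameters independently (Beta
for probabilities/utilities, Gamma with rate parameterization for costs,
using the published shape parameters), holds everything else fixed —
mortality, discount rate, WTP and the navigation purchase price have no
published distributions — evaluates both arms per draw with shared draws
for shared parameters, and summarizes the PSA ICER as the ratio of means
mean(Δcost)/mean(ΔQALY).  The ratio of means is the default because
per-sample ratios are unstable when ΔQALY draws approach zero (the
utility distributions overlap heavily, so they do); the mean of ratios
is also reported.  Acceptance uses NMB > 0 rather than a literal
ICER-below-WTP comparison to handle negative-quadrant draws.
`ceac()` reuses the stored sample set across the whole WTP grid.

Two numerical notes on the published distribution table: the Gamma β
column is a rate (2.13/0.000039 ≈ 54,600 reproduces the printed mean),
and the THA-utility row Beta(3999.4, 2666.3) implies sd 0.006 rather
than the printed 0.06 — the package uses the shape parameters as given
and documents the inconsistency in its tests.  No truncation is applied
to the heavily skewed Beta(3.44, 0.16) safe-zone distribution.

```{r psa, eval = FALSE}
ps <- run_psa(p, volume = 200, n_samples = 1000, seed = 1)
ps
head(ceac(ps))
```

## Verification

Beyond unit tests, two independent routes check the engine:

* `run_microsim()` pushes individual patients through the identical
  event sequence with pseudo-random draws; the cohort totals must sit
  within 3 Monte-Carlo standard errors of the microsimulation means at
  n = 10⁶ (and match exactly when all probabilities are 0 or 1);
* state occupancies must sum to one at every cycle to 1e-12, salvage
  incidence is non-decreasing and bounded by the perioperative survival,
  and QALYs respond monotonically to utilities and hazards (checked over
  randomized parameter sets from `random_parameter_set()`).

## What the synthetic data do and do not cover

`flat_life_table()`/`gompertz_life_table()` generate the background
mortality the source cites but does not print, and `scenario_spec()` /
`random_parameter_set()` produce ±50% perturbations for property tests.
These exercise the model's arithmetic, invariants and calibration
recovery; they do not validate the clinical inputs themselves (pooled
odds ratios, utility mappings, national cost surveys), so passing tests
certify faithful computation, not real-world effect sizes.

## Known limitations and open discrepancies

* The published high-volume results embed an internal inconsistency: the
  printed ICER-by-volume line together with the printed arm costs
  implies a navigated-to-traditional THA-cost ratio of about 0.69, while
  the printed salvage rates imply about 0.77 — and the cohort structure
  (arms differing only in their initial safe/unsafe split) can only
  produce the latter.  No convention setting reconciles both.  The
  package therefore reproduces the reference case, the medium- and
  low-volume results and thresholds, while its 300-case ICER comes out
  about 3% above the printed value and its safe-zone threshold at 200
  cases about 2 points below; the corresponding checks are left failing
  by design rather than tuned away.  The same structural fact makes the
  published high-volume purchase threshold (¥12,624,617) inconsistent
  with any per-case allocation, under which it must be 1.5× the
  medium-volume threshold; the package reports the structural value and
  flags the discrepancy.
* A 5-year horizon with a single salvage pathway (THA, never revised):
  no re-nailing, no conservative management, no lifetime extrapolation,
  no sex-stratified mortality.
* Utilities derive from a linear Harris-Hip-Score mapping pinned to two
  published points; the PSA widths, not the mapping, carry that
  uncertainty.
* Problem sizes used throughout (5 cycles, 1,000 PSA samples per seed,
  10⁶ microsimulation patients, 0.001 calibration grid step) are the
  analysis defaults; all are parameters.
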