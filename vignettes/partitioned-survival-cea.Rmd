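---
title: "A partitioned survival model for the cost-effectiveness of SABR in oligometastatic cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A partitioned survival model for the cost-effectiveness of SABR in oligometastatic cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pscea)
```

## The model

`pscea` implements a three-state partitioned survival model for comparing
stereotactic ablative radiotherapy (SABR) added to standard care against
standard care (SC) alone in oligometastatic cancer. Patients start in the
oligometastatic disease state (OMD), may progress to polymetastatic disease
(PMD), and may die; death is the only absorbing state. In a partitioned
survival model the state occupancies are not derived from transition
probabilities but read directly off the two survival curves at each cycle:

* OMD(t) = PFS(t)
* PMD(t) = OS(t) − PFS(t)
* dead(t) = 1 − OS(t)

with overall survival OS and progression-free survival PFS. This construction
assumes the two curves are internally consistent (PFS ≤ OS); the package
enforces that ordering explicitly and warns when it has to clip.

The cycle length is one month. Per cycle, each arm accrues

* ongoing state costs: `(OMD · c_OMD + PMD · c_PMD) · s / 12`, where `c_OMD`
  and `c_PMD` are annual care costs (USD/year) and `s` is the arm's
  systemic-therapy fraction (see *Cost scaling* below);
* QALYs: `(OMD · u_OMD + PMD · u_PMD) / 12`, with utility weights on the
  dead/full-health 0–1 scale;
* end-of-life cost: a lump sum `c_EOL` on each cycle's increment of the dead
  state (patients alive at the horizon never accrue it).

One-time items are charged undiscounted at the start of the simulation: the
primary SABR course (intervention arm), the expected per-patient salvage cost
`(salvage_RT / arm_size) · c_RT + (salvage_SABR / arm_size) · c_SABR`, the
one-time adverse-event cost, and a one-time adverse-event disutility stored as
a positive magnitude and subtracted from the QALY total. Charging the salvage
bulk at t = 0 follows the source analysis, which had no administration dates;
it slightly overstates their present value.

Both costs and QALYs are discounted at 3%/year by default, using
`(1 + r)^(−t/12)` evaluated at mid-cycle (t = month − 0.5).

Arms are compared by incremental cost ΔC, incremental effect ΔE, the
incremental cost-effectiveness ratio ICER = ΔC/ΔE, and net monetary benefit
NMB = E · λ − C at willingness-to-pay λ ($100,000/QALY by default). The ICER
is only reported in the quadrants where it is interpretable; a cheaper, more
effective intervention is flagged *dominant* rather than given a negative
ratio.

## Survival curves from annual anchors

The bundled input set (`sabr_comet_inputs()`) carries each arm's OS and PFS as
annual anchor points, as published. The package expands anchors to the monthly
grid by **constant-hazard (piecewise exponential) interpolation**:

S(t) = S(a) · (S(b)/S(a))^((t−a)/(b−a)) for anchors a ≤ t ≤ b.

Constant hazard rather than linear interpolation was chosen because survival
is multiplicative in time, the rule is closed under re-interpolation (a
piecewise-exponential curve sampled anywhere and re-interpolated reproduces
itself exactly, which makes the splice operation below self-consistent), and
it reproduces the underlying trial's published medians well. Two edge
conventions: beyond the last anchor the last value is carried flat (the
published table repeats its year-5 value at year 6 in the same spirit), and an
anchor at survival 0 implies infinite hazard on its interval, so interpolated
values drop to 0 immediately after the preceding anchor.

This interpolation is the package's declared approximation of record. The
source analysis read monthly values off digitized Kaplan-Meier curves that are
not published; annual anchors cannot recover the within-year shape of those
curves. The effect is asymmetric across arms — the standard-care arm's steep
early decline loses more within-year area than the intervention arm's — so
per-arm totals rebuild more faithfully than small between-arm differences
(incremental cost in particular is a small difference of ~$300k totals). The
acceptance checks in `tests/testthat/test-acceptance.R` state the published
values with their tolerances and are left failing where this approximation
moves a quantity outside its band, rather than compensating with a different
accrual convention.

### Mid-cycle correction

State membership per cycle is evaluated at mid-cycle (the mean of month-start
and month-end occupancy), the discrete analogue of a half-cycle correction.
The package treats a 30-step-per-month numerical integration of the same
accrual as its reference: the monthly engine is required (and tested) to agree
with it within 1%. Start- or end-of-cycle accrual would miss that bound on
these curves.

## Cost scaling

The source describes scaling ongoing care costs by each arm's
systemic-therapy fraction (55% intervention, 63.6% comparator) with costs
"distributed proportionally" between states — wording that is genuinely
ambiguous. `econ_settings(cost_scaling_mode =)` therefore exposes both
readings: `"systemic_fraction"` (default; annual state costs multiplied by the
arm's fraction) and `"none"`. The default reproduces the published per-arm
totals to within a few percent, the alternative overshoots them by ~40%, which
is why the fraction-scaling reading is the default.

## Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `annual_omd_cost` | 97,440 | USD/year | ongoing care, progression-free state |
| `annual_pmd_cost` | 189,840 | USD/year | ongoing care, progressed state |
| `end_of_life_cost` | 19,174 | USD | last-180-days lump sum at death |
| `palliative_rt_unit_cost` | 11,070 | USD/course | salvage radiotherapy |
| `sabr_unit_cost` | 11,700 | USD/treatment | primary and salvage SABR |
| `u_omd`, `u_pmd` | 0.82, 0.59 | utility | progression-free / progressed |
| `annual_discount_rate` | 0.03 | /year | costs and QALYs alike |
| `wtp` | 100,000 | USD/QALY | willingness-to-pay |
| `horizon_months` | 72 | months | 192 for the long-term analysis |
| arm sizes | 66 / 33 | patients | the trial's randomized group sizes; they only enter as denominators for expected salvage costs |

All inputs can be supplied via a YAML configuration (`read_cea_config()`),
which validates field names, ranges and curve monotonicity, and defaults an
omitted willingness-to-pay to $100,000/QALY.

## Long-term extrapolation

For horizons beyond the trial follow-up, OS is extended by **splicing**: the
extended curve follows the trial curve to its end T and then continues along a
long-term reference curve, entered at the earliest time t\* where the
reference passes through the trial's final survival value (t\* is solved under
the same constant-hazard rule; ties break to the earliest time, so a flat
trial tail spliced onto itself continues flat). PFS is extended
**proportionally**: the trial-end ratio r = PFS(T)/OS(T) multiplies the
extended OS beyond T (r = 0 when PFS(T) = 0). Since r ≤ 1, the extended PFS
can never exceed the extended OS.

The published long-term analysis used pooled registry (SEER) curves that are
not printed anywhere, so the package ships a **synthetic** stand-in:
`generate_reference_survival()` mixes parametric survival functions for four
entities (lung, prostate, colorectal, breast) weighted 0.375/0.333/0.188/0.104
— their relative frequency among the four most frequent entities in the
underlying trial. The mixture of a Weibull and three exponentials produces the
qualitative features the splice needs (smooth, strictly decreasing through any
realistic trial-end survival value, mild decelerating hazard from population
heterogeneity). It is labelled synthetic in every output and is **not** a
registry estimate; consequently the published long-term numbers are not
reproduction targets here, and the long-term pipeline is validated by
properties instead (junction continuity, monotonicity, exact agreement with
the closed form on an exponential reference, a clean 192-month run).

## Deterministic sensitivity analysis and threshold search

`one_way_dsa()` re-evaluates the full base case at each range endpoint, one
parameter at a time. Cost and utility ranges follow the published table
(±20% for costs — except the SABR unit cost, whose published range is
8,190–14,040 — and the published utility intervals). The published table
attaches "±15%" to the survival probabilities without saying how annual
anchors were varied jointly; the package applies a single multiplicative
factor to all of a curve's anchors (time 0 excluded), clips to [0, 1] and
re-enforces monotonicity.

The tornado metric is the ICER, matching the published figure, but ICERs are
undefined at endpoints that cross into dominance. Such endpoints are reported
as `NA` with their dominance status, and rows containing one sort last (an
ICER bar cannot be drawn for them); `metric = "inmb"` gives the
always-defined incremental-NMB tornado and is the recommended metric whenever
ΔE or ΔC can change sign. On the bundled inputs, the survival-curve factors
dominate every metric's ranking and several cost endpoints cross into
dominance — the published tornado, which shows the two annual state costs on
top, is only recovered if the survival curves are excluded from the parameter
set, suggesting the published analysis varied them separately or not at all.
The corresponding rank check in the acceptance suite is asserted as stated and
left failing rather than silently dropping the survival rows.

`threshold_search()` finds the SABR unit cost at which incremental NMB reaches
zero, by bisection to $1. The substituted cost applies everywhere the unit
price enters — the primary course and both arms' salvage SABR — so the total
cost is linear in it and the bisection result matches the closed form
`c* = c_base + iNMB_base / (1 + salvage_sabr_count / arm_size)` (the test
suite checks this identity). Note that the published threshold is numerically
consistent with scaling the primary course only; applying the price to salvage
courses as well (as the published narrative describes) yields a somewhat lower
threshold.

## Probabilistic sensitivity analysis

`run_psa()` performs second-order Monte Carlo. Distribution families follow
the published table: gamma for costs, beta for utilities, disutilities and
survival anchors. The published analysis does not state a parameterization;
the package moment-matches, reading each (low, high) range as a 95% interval:

* sd = (high − low) / (2 · 1.96);
* beta: α = m(m(1−m)/sd² − 1), β = (1−m)(m(1−m)/sd² − 1), with an explicit
  error when the implied variance is infeasible (sd² ≥ m(1−m)) directing the
  user to the `degenerate` family;
* gamma: shape = (m/sd)², scale = sd²/m, so shape·scale = m exactly.

Moment matching was preferred over quantile matching for closed-form
testability: the fitted moments round-trip to machine precision and are
asserted in the test suite.

Sampling scheme (the published analysis is silent on all three points, so
these are package decisions):

* parameters shared by both arms — state costs, end-of-life cost, unit costs,
  utilities — are drawn **once per iteration** and applied to both arms, as a
  cohort model requires; arm-specific items (adverse-event cost and
  disutility, each arm's curves) are drawn per arm;
* survival anchors are drawn independently per anchor from a beta centred on
  the base value with a relative ±15% range, then repaired to a valid curve by
  a sequential minimum; a repair that moves any anchor by more than 0.2 logs a
  warning. Anchors at 0 (and anchors numerically too close to 1 for the
  implied beta variance) are left unvaried;
* after drawing, PFS anchors are clipped to the OS anchors. Because
  constant-hazard interpolation is log-linear between anchors, anchor-wise
  dominance implies monthly dominance, so no further clipping can occur
  downstream.

Degenerate distributions reproduce the base case bit-for-bit (tested), the
draw sequence is a pure function of the seed, and the seed is recorded in the
result and every report manifest. Acceptability at λ is the share of
iterations with positive incremental NMB; the dominant-strategy share counts
iterations with ΔC < 0 and ΔE > 0.

## Numerical choices

* Curve validation tolerances: pooling weights must sum to 1 within 1e−9;
  occupancy conservation is asserted at 1e−9 per month; the arms are declared
  `equivalent` when |ΔE| < 1e−12.
* Bisection: $1 absolute tolerance on the threshold cost; a bracket without a
  sign change is an error reporting both endpoint values, never a guess.
* Junction solving in `splice_extrapolate()` inverts the reference piecewise
  under constant hazard and breaks ties at the earliest time.
* Degenerate inputs: a trial curve ending at survival 0 cannot be spliced
  (error); OS(T) = 0 with PFS(T) > 0 makes the proportionality ratio undefined
  (error); a reference that never reaches the trial-end survival is an error
  instructing the user to supply longer support.

## What the synthetic generators do and do not show

`generate_random_model_inputs()` produces random valid input sets (monotone
OS, PFS = OS × a non-increasing random fraction, ordered utilities, positive
costs) used to property-test occupancy conservation, dead-state monotonicity
and engine stability across 1,000 seeds. Together with the synthetic reference
curve, these exercise every code path without any external data. What passing
those tests does **not** show: that the synthetic reference resembles real
registry survival for any cancer entity, or that the model's outputs at the
16-year horizon approximate the published long-term results — both would
require the unpublished pooled registry curves. Trial-duration results depend
only on published inputs and are checked directly against the published
values at stated tolerances.

## Problem sizes

The test suite runs the PSA at its published size (n = 10,000, fixed seed),
property sweeps at 300–1,000 seeds, and the integration oracle at 30 steps per
month; `scripts/acceptance.R` recomputes the headline quantities at the same
sizes. A full suite run takes well under a minute on one CPU.

## Known limitations

* Annual anchors cannot recover within-year Kaplan-Meier shape; small
  incremental quantities (ΔC, and through it the ICER and the PSA dominance
  share) inherit most of the resulting error, while per-arm totals are
  reproduced much more closely.
* The one-time salvage and adverse-event items are undiscounted at t = 0 by
  construction, as in the source analysis.
* No efficiency-frontier analysis for more than two strategies, no
  value-of-information analysis, and no correlation structure between PSA
  parameters beyond the shared-draw scheme described above.
* The long-term mode is only as good as the reference curve supplied to it;
  the bundled reference is a labelled synthetic stand-in.
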