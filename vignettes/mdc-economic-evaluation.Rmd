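---
title: "Methods: economic evaluation of a multidisciplinary lung cancer clinic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: economic evaluation of a multidisciplinary lung cancer clinic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdcecon)
```

This vignette documents the models implemented in `mdcecon`, the
assumptions and conventions behind them, what the synthetic cohort
generator does and does not emulate, and the design choices made where the
design was genuinely open. All monetary quantities are 2019 Canadian
dollars (CAD).

## The evaluation problem

A multidisciplinary clinic (MDC) lets a patient with a newly diagnosed lung
cancer see respirology, medical oncology and radiation oncology in one
consolidated visit instead of through sequential referrals. The evaluation
compares two cohorts — 78 patients under the traditional model and 350
under the MDC — and asks three questions:

1. Did resource utilization change (oncology visits from diagnosis to first
   treatment, biopsies, staging imaging, invasive mediastinal staging)?
2. What is the monetary value of the avoided visits, from the societal
   perspective (all costs counted regardless of who pays: patient
   out-of-pocket, patient and caregiver productivity, administrative time)?
3. The MDC substantially increased guideline-recommended invasive
   mediastinal staging by EBUS-TBNA for stage-2/3 disease (15% to 60% of
   eligible patients) — is that added spending cost-effective?

## Visit-savings cost model

With `d` the difference in mean oncology visits per patient between arms
(base 2.68 − 1.62 = 1.06) and `n` the MDC cohort size (350), the model
prices `V = round(d * n)` avoided visits (371). Components, for caregivers
per visit `g` (1.25), working-age patient fraction `p` (0.23), hours per
visit `t` (clinic 1.26 h + forgone travel/parking/wayfinding 1.27 h), wage
`w` (29.55/h) and employed caregiver fraction `e` (0.50):

* out-of-pocket: parking `V * 6.00` and return travel `V * 59.14`;
* patient productivity (human-capital approach): `V * p * t * w`;
* caregiver productivity: `(g * V) * e * t * w` — the caregiver visit count
  `g * V = 463.75` is kept **unrounded** inside the formula (rounding it to
  the displayed 464 first would inflate the component by CAD 10);
* administrative booking time: `V * 1.37` (3 min of clerk time per visit).

The under-65 fraction is applied as a fraction of visits, not as an integer
subset of patients. Travel may alternatively be specified as distance ×
allowance rate (102 km × 0.58/km = 59.16); the published per-visit cost
59.14 differs from that product by two cents and is taken as the canonical
default, with distance mode available for cohort-driven runs.

Extrapolation to a larger program volume multiplies the *unrounded*
per-patient grand total by the target size; at 585 patients this gives
CAD 80,880, matching the published three-year projection within 0.01%.
The 22-month study framing is annotation only; no discounting is applied.

### Rounding conventions

All intermediates are carried unrounded; only reported dollar fields are
rounded, halves away from zero. The source tables are themselves not
reducible to a single rounding rule, and the package follows their
arithmetic exactly:

* line items (parking, travel, each productivity component, admin) round
  the exact value to the nearest dollar;
* the **productivity subtotal** is the sum of the two *rounded* components
  (6,379 + 17,335 = 23,714, not round(23,714.72) = 23,715);
* the **out-of-pocket subtotal** rounds the *exact* sum (this is what the
  best-case scenario and the EBUS tables require: 371 × 4.50 = 1,669.50
  would round up as an item but the subtotal 23,610.44 rounds down);
* the grand total sums the three subtotals; per-patient values divide the
  rounded total by `n` and round.

With these conventions the base case reproduces every published line to
the dollar (grand total 48,389; 138/patient), and the sensitivity endpoints
reproduce 37,173 and 122,896 exactly.

## Multi-way sensitivity analysis

`scenario()` objects override named parameters; `evaluate_scenario()` is a
pure function of the merged parameter set, so evaluation order is
irrelevant. The two published scenarios are encoded as:

* **best case** — 55.5-minute clinic visit (time forgone unchanged at
  1.27 h), parking 4.50, 25% caregiver employment;
* **worst case** — parking 12, a flat 7.5 h (a full working day) off work
  replacing clinic + forgone time for *both* patients and caregivers, 75%
  caregiver employment. Under this convention the 94.8-minute worst-case
  clinic-visit duration affects no monetary component, and the endpoint is
  reproduced exactly; the flat-hours override (`hours_off_work_override`,
  with `override_applies_to`) exists precisely for this scenario shape.

Travel cost is held at base in both scenarios. Probabilistic (Monte-Carlo)
sensitivity analysis is out of scope: the source analysis is deterministic.

## EBUS-TBNA threshold analysis

Per arm (traditional: 3 procedures among 20 eligible stage-2/3 patients;
MDC: 57 among 95), pathway cost = procedures × 1,577 (conscious-sedation
procedure cost) + out-of-pocket (parking 9.00 × 50% of patients requiring
it + travel 59.14, per procedure) + productivity (7.5 h forgone at
29.55/h, for the under-65 fraction of staged patients — 1/3 and 19/57,
applied unrounded — plus one caregiver per procedure at 50% employment).
QALYs are procedures × 0.071; an alternative published weight of 0.015 is
accepted as a configuration value but is not the default, being drawn from
a setting less comparable to a Canadian single-payer context.

The ICER divides the incremental cost by the *unrounded* incremental QALYs
(4.047 − 0.213 = 3.834), giving ≈ CAD 25,709/QALY; the displayed QALY
difference (3.84) rounds per-arm QALYs to two decimals before subtracting,
matching the published presentation. The threshold quantity is
`ΔQALY_needed = ΔCost / WTP` (≈ 1.23 at WTP 80,000/QALY); the inverse
relation `ΔQALY_needed × WTP = ΔCost` holds exactly. A zero incremental
QALY yields an explicit undefined-ICER flag, never a number.

Two small discrepancies exist in the published per-item table (traditional
out-of-pocket prints 192 where the inputs give 191; MDC patient
productivity prints 4,207 where 19 × 7.5 × 29.55 = 4,210.88): the package
reports the recomputed values, which agree with the printed arm totals
(5,476 and 104,039) and ICER (25,708) within 0.1%, and does not force the
printed figures.

## Synthetic cohort generator

The generator emulates the two arms' *marginal* structure so the pipeline
is testable without patient data. In **calibrated** mode (the default)
every integer quantity is allocated deterministically:

* stage, diagnosis and caregiver-count compositions by largest-remainder
  allocation of the target proportions;
* per-arm-per-stage visit counts by even allocation of the target sum
  `round(mean × n)` (values `q`/`q+1`), so each stratum mean matches its
  target within `1/(2n)`;
* EBUS flags for the first `round(rate × n_eligible)` stage-2/3 patients,
  treatment flags likewise per published per-stage rate;
* distances as lognormal quantiles rescaled to hit the 102 km mean
  exactly; ages as truncated-normal conditional quantiles with the
  under-65 count enforced exactly (79/350 in the MDC arm).

Arm-level visit means include the small undetermined-stage groups (5
traditional, 3 MDC patients), which are excluded from all per-stage and
treatment subgroup analyses. Their mean visits are not published; the
defaults (3.6 and 7/3) are calibrated so each arm total equals
`round(arm_mean × n)` — the only choice consistent with the published
all-patient means (2.68, 1.62) and the 1.06 visits-saved rate.

In **sampled** mode, visits are `1 + Poisson(mean − 1)` truncated at 8
(visit counts are small positive integers and no dispersion is published —
both the shape and the ceiling are configurable stand-ins), utilization
counts are Poisson, distances lognormal (sdlog 0.6, configurable; only the
mean is published), ages truncated normal on [18, 100], and flags
Bernoulli. Sampling is seed-deterministic and leaves the session RNG state
untouched.

What calibrated tests therefore show is that the pipeline *reproduces the
published marginals it was given*; they do not validate distributional
shape, within-patient correlation (e.g. age × staging — the published
under-65 fractions of staged patients are used as unit variables rather
than derived from synthetic ages), wait-time dynamics, or any temporal
structure, none of which the generator models.

## Statistical comparisons

Two-sample mean comparisons default to Welch's t-test (the source states
only "unpaired t-tests"; the equal-variance variant is available by flag).
The 2×2 test defaults to chi-squared without continuity correction,
switching to Fisher's exact test when any expected count is below 5. A
one-way ANOVA wrapper is provided for k-group contrasts; no published
figures anchor it. No multiple-testing adjustment is applied, matching the
unadjusted published p-values. The chi-squared p-value is cross-checked in
the test suite against a margin-conditioned permutation oracle
(hypergeometric resampling of the 2×2 table, mid-p convention for ties
against the continuous asymptotic reference).

## Problem sizes and numerical choices

Calibrated cohorts are 428 patients (78 + 350); property-style invariants
run on 1,000 randomized parameter draws (additivity), 200 (linearity) and
100 (monotonicity), with 100 seeds for sampled-mode marginal recovery and
10,000 permutation resamples for the contingency-table oracle. These sizes
make the full suite run in well under a minute while keeping Monte-Carlo
standard errors far below the tested tolerances. Dollar rounding uses
half-away-from-zero with a 1e-9 guard against binary-representation
artifacts; validation failures always name the offending field.

## Known limitations

The cost model is linear and deterministic: no discounting, no childcare
or meal costs (explicitly uncaptured in the source), no physician-billing
effects (unchanged between models), and no survival or downstream staging
consequences of the added EBUS-TBNA (discussed only qualitatively in the
source). Extrapolation assumes per-patient savings scale linearly with
volume. The synthetic cohort is a marginal emulation, not a resample of
real data; conclusions about real-world heterogeneity should not be drawn
from it.
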