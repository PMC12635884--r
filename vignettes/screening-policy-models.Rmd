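---
title: "Models behind agescreen: cohort calibration, eligibility, and policy arithmetic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models behind agescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agescreen)
library(dplyr)
```

agescreen is a desk-scale policy-modelling toolkit for age-based low-dose CT
(LDCT) lung cancer screening. Its starting point is a well-known problem:
the 2021 USPSTF eligibility rule (age 50–80, ≥20 pack-years, currently
smoking or quit <15 years) conditions screening on tobacco exposure, yet a
large fraction of incident lung cancers — never-smokers, light smokers, and
long-quit former smokers — falls outside it. The package provides the pieces
needed to study what happens when the rule is widened or replaced by a pure
age criterion: a calibrated synthetic patient cohort, a rule engine, survival
validation utilities, a stage-shift mortality model, a Monte Carlo
cost-effectiveness engine, a screening-harms cascade, and a BEIR VII-style
radiation-risk model. This vignette documents the models, their assumptions,
the defaults, and the numerical choices.

## The synthetic cohort

No patient-level data ship with the package. `generate_cohort()` draws a
997-patient cohort whose *aggregate* structure matches the published
institutional cohort the models were calibrated to:

* the nine eligibility strata (350 USPSTF-eligible; 647 ineligible, split
  into age-only 41, cessation-only 134, pack-years-only 65, age+cessation 32,
  age+pack-years 15, pack-years+cessation 89, age-eligible never-smokers 195,
  all-criteria 76);
* the capture counts of the expansion scenarios: a pure age-based 40–85 rule
  captures 936/997 (61 patients have ages outside 40–85), and the combined
  expanded rule (40–85, ≥10 pack-years, no cessation limit) captures 619/997;
* 247 never-smokers overall;
* group-level marginals for sex, race, ethnicity, stage and histology.

These counts hold *by construction*, not in expectation: the calibration
stores member-level sampling cells that jointly fix each patient's age band,
pack-year class and smoking status, and generation fails loudly (a
`calibration-infeasible` error naming the violated target) if a modified
calibration cannot reach its own targets. Continuous covariates are then
sampled within cell constraints — ages uniformly over the feasible integer
range, pack-years and quit-times from log-normals moment-matched to the
published medians/IQRs (eligible-group pack-years median 40, IQR 30–55;
cessation beyond the 15-year limit mean 24 y) and truncated to the cell
bounds.

Three allocation questions are not settled by the published tables, and the
generator takes a documented position on each:

* **Age placement.** 164 patients sit in age-excluded strata but only 61 may
  have ages outside 40–85. The 61 are split 13 below age 40 and 48 above 85,
  proportional to the published 9-below-50 vs 32-above-80 split of the
  age-only stratum (which the generator reproduces exactly), and assigned to
  strata by a fixed integer allocation.
* **Never-smokers outside the age window.** The 52 never-smokers who are not
  age-eligible are placed in the all-criteria stratum (76 = 52 never-smokers
  + 24 smokers failing all three criteria); a never-smoker's reason set
  `{age, never_smoker}` maps there.
* **Expansion increments.** The published per-expansion increments (33, 41,
  130, 58) sum to 262, not to the 269 implied by the printed totals
  (619 − 350). The generator calibrates exactly to the totals and treats the
  increments as soft targets: its realised increments are 33 (age), 41
  (pack-year floor), 134 (cessation limit — all members of that stratum are
  captured once the limit is dropped), and 61 from the multi-criterion
  strata.

Some published marginals are internally inconsistent at the ±1 level
(a histology column summing to 349, race columns to 341/638, a handful of
unknown stages); the generator resolves these by adding the remainder to the
largest or least-specified category and records the reconciliations here.

Pack-year exposure is generated for everyone, but 263 nonguideline records
(all 247 never-smokers plus 16 heavy-smoking long-quit patients) carry
`pack_years_observed = FALSE`, mirroring the published count of unknown
exposure histories. The classifier is permissive by default and offers a
strict mode (`unknown_pack_years = "ineligible"`) for sensitivity analyses of
self-report error.

### Survival embedding

Each group gets a Weibull survival law with a shared shape parameter. The
shape is solved from two published anchors — a nonguideline-vs-guideline
hazard ratio of 0.67 and median overall survival of 9.5 vs 4.4 years:

$$k = \frac{\log 0.67}{\log(4.4/9.5)} \approx 0.520,\qquad
  \sigma_g = \frac{4.4}{(\log 2)^{1/k}},\quad
  \sigma_n = \frac{9.5}{(\log 2)^{1/k}},$$

so *both* medians and the hazard ratio hold exactly in the generating law
(a shared-shape Weibull pair is proportional-hazards with
HR $=(\sigma_g/\sigma_n)^k$). Administrative censoring is uniform on
(1, 20) years, chosen once to give roughly 45% censoring, a typical fraction
for a retrospective cohort with staggered entry. The parameter-recovery
checks use 10,000 patients per arm, a size at which the Cox estimate of the
log-HR has a standard error of about 0.02 and the Kaplan-Meier medians are
estimated to well within half a year; the full test suite and the
reproduction script both run in minutes at these sizes.

What passing these checks shows — and does not show: the generator proves
that the rule engine, the survival machinery and the calibration are
mutually consistent, and it exercises every classifier path on realistic
joint distributions. It does not validate the published study itself; the
synthetic cohort has no correlation structure beyond what the cells impose
(e.g. smoking status and sex are independent within group), no real
histology-survival association, and its censoring pattern is simpler than a
real registry's.

## Eligibility semantics

Boundary conventions follow the wording of the guidelines: age bounds are
inclusive at both ends; the pack-year floor is inclusive (≥); the cessation
limit is exclusive (quit *strictly less than* 15 years ago passes, quit
exactly 15.0 years fails, matching the "quit >15 y" stratum label on the
other side). `ineligibility_reasons()` reports the failed criteria as a set
and never-smokers fail on smoking history as a whole, so the eight published
ineligibility strata are exactly the images of the possible reason sets.

## Stage-shift model

`lives_saved()` maps a national stage I detection rate to annual lung-cancer
deaths averted. The published scenario table provides five (rate, lives)
pairs, but no single smooth curve passes through them — the implied slopes
between adjacent rows differ several-fold, and the underlying model's
parameters are not published. The package therefore anchors a piecewise-linear
curve at the two headline cells, (16%, 3,650) and (30%, 26,124), runs it
linearly from the origin below the first anchor, and extrapolates the final
segment's slope above the second. This keeps the curve monotone and
continuous, makes `parity_rate()` an exact inverse (tested to 1e-6), and
reproduces the two cells that the cost-effectiveness engine relies on. On
this calibration the parity points with the breast (10,660 lives/year) and
colorectal (13,650) benchmarks fall at 20.4% and 22.2% stage I detection —
close to, but not exactly, the published 21.4%/22.3%, which were produced by
the unpublished model. Alternative anchor sets can be supplied through
`stage_shift_params()`.

The number needed to screen is the reciprocal of the absolute risk
reduction, reported as an integer (half away from zero) with the exact
reciprocal alongside.

## Cost-effectiveness engine

`run_cea()` is a program-level Monte Carlo engine. Each configured program
(lung at 14.4% and at 70% participation, breast, colorectal) is parameterised
by its published annual cost, lives saved, and — for lung — all-cause lives
saved (a 6.7% all-cause mortality reduction variant), each with a published
95% CI. Per iteration:

* annual cost and lives saved are drawn from Gamma distributions
  moment-matched to the mean and CI (costs and counts are positive and
  right-skewed; the published intervals are treated as ±1.96 SD);
* the QALY weight is drawn from a normal with mean 0.85, SD 0.05, truncated
  at zero;
* cost per life saved and the ICER per QALY are computed per iteration;
  point estimates are iteration means and intervals are 2.5/97.5
  percentiles.

The discounted life-year stream per death averted is not published. It is
back-solved once so that the lung point-estimate ICER at 14.4% participation
equals $85,000/QALY (with 3% annual discounting and the 0.85 weight), then
held fixed — a choice that makes the engine's one free parameter explicit.
Held fixed, it independently reproduces the published $107,000/QALY at 70%
participation. The comparator programs are benchmark inputs, not re-derived
models: their QALY gain per death averted comes directly from their published
cost per life saved and ICER. (For colorectal, that published pair implies a
QALY gain per death larger than any 3%-discounted life-year stream can
produce, one of several internal tensions in the source arithmetic; treating
the comparators as inputs sidesteps it.)

When participation or the stage I detection rate are overridden, means
rescale: cost proportionally to participation, lives proportionally to
participation times the stage-shift curve ratio. The two published lung
columns are *separate* calibrated programs — their printed costs are not
exactly volume-proportional to each other, so cross-column scaling is not
claimed.

Rounding of cost per life saved follows the published precision: one decimal
below $100k, whole thousands to $200k, nearest $10k above.

### Cost neutrality

The published claim that the program becomes cost-neutral at 76%
participation through treatment savings alone cannot be recovered from the
published table arithmetic: gross savings of $24.76B/year at 70%
participation already exceed the $12.8B program cost, so a linear net-cost
model in participation has no root near 0.76. `cost_neutral_participation()`
therefore solves a documented three-parameter model — fixed program cost
($2.6B, the published infrastructure figure), variable cost per unit
participation implied by the 70% column, and a savings-realization fraction
(≈0.51) back-solved once from the 76% anchor (interpretable as the share of
modelled gross savings actually realised after lead time and adoption lags).
The solver itself is a bracketed bisection with the documented degenerate
behaviours: zero savings means a positive net cost everywhere (reported, no
root); doubling savings strictly lowers the root.

## Harms cascade

Per person screened, lung LDCT screening is modelled with a 14.7%
false-positive rate, 1.2% invasive procedures for benign disease, and 0.004%
complications (the published per-person figure; the published counts imply
0.0045%, a rounding gap noted here and absorbed by the test bands on
counts). Totals are population × participation × per-person rate, so they
are exactly linear in participation and the per-person rates are
participation-invariant — this denominator choice (participation × 155.5M
eligible adults) is the only one that reproduces the published 3.3M and
16.0M false-positive totals. `cascade_mc()` adds Beta-distributed rate
uncertainty moment-matched to the published CIs.

## Radiation risk

`lar()` implements a lifetime-attributable-risk model with the BEIR VII
preferred lung-model structure: sex-specific ERR (0.32/1.40 per Sv,
male/female) and EAR (2.3/3.4 per 10⁴ person-year-Sv) coefficients, an
exposure-age modifier $e^{\gamma e^*}$ with $e^* = (\min(e,30)-30)/10$,
attained-age powers $(a/60)^{-1.4}$ (ERR) and $(a/60)^{5.2}$ (EAR), a
5-year latency, DDREF 1.5, and a log-scale blend weighting the ERR
projection 0.3. Competing mortality enters as conditional survival
$S(a)/S(e)$ from a synthetic abridged life table shipped as a plain-text
fixture (Gompertz-Makeham survival and a stylised baseline lung-cancer
mortality curve; it is labelled synthetic and swappable). Integration is
annual from exposure age + latency to 100.

Because the exact parameterisation behind the published per-sex risks is not
printed, a final per-sex multiplier is fitted once so the default decennial
40–85 schedule (5 scans, 6.5 mSv) reproduces the published 0.04% (men) and
0.05% (women); the multiplier is stored openly in the coefficients object
and does not affect any structural property. The model is linear in dose,
additive over scans, and strictly decreasing in the age at first exposure
over the screening-relevant range — all tested. The published per-start-age
benefit-to-risk band (108–284 lung-cancer deaths prevented per
radiation-induced cancer death) requires a per-age decomposition of program
benefit that the published material does not provide; the package exposes
the plain ratio (`benefit_risk()`, reproducing the program-level 1,800
summary) and leaves the per-age decomposition out of scope.

## Sensitivity analysis

`one_way()` and `scenario()` wrap any engine that is deterministic given a
seed. Each sweep evaluation is re-seeded with a deterministic hash of the
base seed and the parameter value, so Monte Carlo noise cannot masquerade as
parameter sensitivity and a singleton sweep is bit-identical to the
corresponding scenario run. Overrides use dotted paths into the parameter
list and must name existing parameters; conflicting overrides are an error.

## Reproducibility and problem sizes

Every stochastic entry point takes an explicit seed and restores the
caller's RNG state. Default problem sizes are chosen for desk-scale use:
the cohort is the published 997; parameter-recovery checks use 10,000 per
arm; the published Monte Carlo iteration count is 10,000 and the test suite
uses a few hundred iterations where only distributional sanity, not
precision, is at stake. `scripts/acceptance.R` regenerates the headline
quantities from scratch for any seed.

## Known limitations

* The synthetic cohort matches published margins and capture totals, not
  joint distributions; analyses of covariate interactions on it reflect the
  generator's independence assumptions.
* The stage-shift curve is a two-anchor interpolation, not a mechanistic
  stage-specific case-fatality model; interior published scenario rows are
  comparison outputs.
* The cost-effectiveness engine is a one-year program-level model, not a
  lifetime microsimulation; the back-solved life-year stream bundles lead
  time, cure fractions, and discounting into one parameter.
* The radiation model's absolute level is anchored to two published per-sex
  risks; only its structure (dose linearity, age dependence, competing
  mortality) is independently meaningful.
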