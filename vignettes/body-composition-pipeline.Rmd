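---
title: "Methods: the pedibca body-composition pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the pedibca body-composition pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedibca)
```

## What this package models

`pedibca` is a software re-implementation of the computational pipeline of
a portable body-composition analyzer for children aged roughly 6-12. The
physical device combines three sensors — a strain-gauge load cell read
through a 24-bit ADC, a 970-nm near-infrared photosensor, and a
swept-frequency bioimpedance converter driving 0.25 mA at 50 kHz — and
converts their raw signals into six body-composition parameters: BMI,
body-fat percentage (BF%), fat-free mass (FFM), total body water (TBW),
muscle mass (MM) and bone mass (BM). The package implements that chain
exactly as the device computes it, together with the published
cross-parameter prediction models, the device-validation statistics, and
a synthetic-cohort generator so that every stage can be exercised without
hardware or subject data.

## The sensor forward models

**Load cell.** A two-point calibration maps ADC counts linearly to
weight: the slope is `known_load / (counts_loaded - counts_empty)` and
the offset is defined as `slope * counts_empty`, which forces the
zero-load reading to exactly 0 kg. Negative computed weights raise an
error rather than being clamped: a negative weight can only come from a
calibration or sensor fault, and silently clamping would mask it in
downstream estimates.

**Optical chain.** The photosensor voltage `V` relative to the
unattenuated voltage `V0` gives the optical density `OD = -log10(V/V0)`,
the transmission `T = 10^(-OD)`, the verification `V = V0 * T`, and the
optical current `I_OC = responsivity * V`. All logarithms in the chain
are base 10, matching the optical-density definition. Two numerical
conventions are inherited from the device documentation and kept as
printed rather than "fixed": the responsivity is 0.42 (the datasheet
value used in the worked example; an alternative 0.57 V/uW figure
appears in the hardware description but is not used numerically), and
the optical-current step multiplies a voltage by an A/W responsivity and
labels the result amperes. The package evaluates this exactly as the
firmware does — 0.05 V in, 0.021 A (21 mA) out — without reconciling the
units, because the downstream TBW equation was calibrated against that
convention.

**Impedance converter.** The device relation is printed as
`1/Z = (Vout - Vin)/Iload`, whose literal solution is
`Z = Iload/(Vout - Vin)`; the conventional Ohm's-law reading is
`Z = (Vout - Vin)/Iload`. Both are exposed
(`impedance_from_sweep(..., mode = )`), the printed form is the default,
and the mode is recorded on the result. The conventional form is the one
that produces ohm-scale impedances (hundreds of ohms at 0.25 mA) of the
magnitude the FFM and MM equations expect. The returned value is a
magnitude, as reported by the converter's internal DFT.

## The estimation chain

With weight `W` (kg), height `H` (cm; metres only inside BMI), age `R`
(years) and sex code `S` (0 girl, 1 boy):

* `BMI = W / (H/100)^2`
* `BF% = 1.15 BMI - 0.7 R - 3.6 S + 1.4`
* `FFM = 0.742 H^2/Z + 0.151 W + 1.613` — `H^2/Z` is the classic
  bioimpedance "impedance index"
* `MM = 0.401 H^2/Res + S + 3.825 - 0.071 R + 5.102`
* `TBW = 0.698 R + 0.414 H - 0.491 W + 2.638 log10(1/OC) + 14.61`
* `BM = 0.328 W + 0.339 H - 29.533 - MM`

Design choices that were genuinely open:

* The TBW logarithm is taken as base 10 (the only explicit logarithms in
  the source chain are base 10); `log_base = "ln"` is available for
  sensitivity analysis.
* `H` enters every equation after BMI in centimetres, the uniform symbol
  usage of the source.
* The single measured 50-kHz impedance magnitude feeds both the FFM
  ("impedance") and MM ("resistance") equations unless a separate
  resistance column is supplied; the device measures one bipolar signal
  and the two quantities are never distinguished numerically.
* Out-of-range outputs (negative BM, BF% above 100) are emitted with a
  soft warning, not rejected: the published equations can produce them
  and the package reproduces printed behaviour. Errors are reserved for
  domain violations (non-positive impedance, optical current, height).
* The CDC weight-status classifier takes a BMI-for-age percentile as
  input (it never computes one) and uses half-open intervals with the
  upper class winning at the exact cut points: 85 classifies as
  overweight, 95 as obese. The published category table is ambiguous at
  the endpoints; this convention keeps the four categories a partition
  of [0, 100].

Two published inconsistencies are documented rather than repaired: the
BF% equation evaluated at the obese group's mean BMI gives about 21,
far from the published obese BF% mean of 31.3; and the BM equation at
the obese means gives about 4.4 kg versus the published 1.065 kg. The
equations are implemented exactly as printed; consequences for the
synthetic cohort are described below.

## Published prediction models

The six cross-parameter linear models (each parameter regressed on the
other five, N = 200) ship as packaged data, retrievable with
`published_model()`. The regression table is the canonical source. Two
coefficients differ between that table and the running-text equations
(the BMI coefficient of the BF% model, +0.477 vs -0.477, and the BF
coefficient of the FFM model, 0.130 vs 0.310); the table values are
canonical — the study's own conclusions quote +0.477 — and the text
variants stay retrievable via `source = "equation"`. The BM model's BF
coefficient is an explicit zero. The published "Multiple R" and
"R Square" diagnostics are stored verbatim as metadata and never
validated against each other, because several printed pairs are
mutually impossible for OLS (R-squared exceeding R).

Refitting uses ordinary least squares (`stats::lm`) behind
`fit_linear_model()`, and `stepwise_fit()` performs forward selection
with backward elimination on partial-F p-values (enter < 0.05,
remove > 0.10 — the common statistical-package defaults, since the
source names the software but not its thresholds). Ties are broken by
smallest p-value then alphabetically, making selection deterministic for
a given input.

## Agreement statistics

* **Accuracy** per measurement: `(1 - |p - t|/t) * 100` against the
  reference device.
* **Mean accuracy**: `100 - (sum of row percent differences)/(2 * 7)`
  across both groups and the seven validated parameters (weight plus the
  six composition parameters). Fixing the parameter count at 7 exactly
  reproduces the published overall values (94.77% and 0.884) from the
  published group means, which is how that reading of the formula was
  confirmed.
* **Percent difference** between group means is implemented as the
  symmetric form `100 |a-b| / ((a+b)/2)`. The source does not print its
  formula; the symmetric form exactly reproduces six of the nine printed
  rows, and the three mismatches are consistent with row-slip
  typography (two of them match the symmetric values of neighbouring
  rows). Those three cells are excluded from numeric checks and kept
  verbatim in the packaged table.
* **Bland-Altman**: bias and `bias +/- 1.96 SD` limits with the sample
  (n-1) SD.
* **ICC**: two-way random-effects, single-measure ICC computed from the
  explicit sums-of-squares decomposition, absolute agreement by default
  (consistency available), with F-distribution confidence intervals. The
  source names only "inter-rater reliability"; absolute agreement is the
  stricter and more common choice for method comparison, and the form is
  configurable. The test suite cross-checks the mean squares against an
  independent `stats::aov` decomposition.
* **SEM** = `SD * sqrt(1 - ICC)`, the standard definition (the source
  prints the column without a formula).
* The published "relative reliability" and "% mean difference" columns
  have no stated definition and some values exceed any correlation
  bound; they are carried verbatim in
  `published_reliability_table()` and never recomputed.

t-tests, ANOVA, Shapiro-Wilk and Pearson correlations are delegated to
the standard `stats` routines; the package asserts their contracts, not
their internals.

## The synthetic cohort generator

The generator emulates the study conditions: two groups (obese, normal)
of 100 children each with a 50/50 sex split, each parameter drawn from a
truncated normal with the published group mean and SD (weight and height
positive, BF% in (0, 60)). The published tables provide only marginal
means and SDs, so parameters are sampled independently by default; the
published obese-group correlation matrix is packaged, and a
Gaussian-copula mode accepts it as a target correlation for stress
tests — an extension, not a claim about the study population.

Three of the nine parameters (BMI, BF%, BM) are deterministic functions
of the others in the device's forward chain, so no raw sensor frame can
realize independently sampled values for them. The generator therefore
has two modes:

* `mode = "pipeline"` (default): age, sex, height, weight, FFM, TBW and
  MM are sampled; BMI, BF% and BM are derived through the estimation
  equations. Every subject is exactly realizable by a sensor frame, and
  `estimate_all()` after `invert_to_sensors()` is the identity to 1e-9
  per field. Because of the published BF%/BM equation inconsistencies
  noted above, the derived BMI/BF%/BM means do not match the published
  group means in this mode — they cannot, for any sensor input.
* `mode = "table"`: all nine parameters are sampled independently from
  the published marginals, reproducing the published summary table's
  structure without cross-parameter consistency.

Inversion solves each equation backwards: ADC counts from weight and
the calibration, impedance `Z = 0.742 H^2/(FFM - 0.151 W - 1.613)`,
resistance analogously from MM, optical current from the TBW relation,
and the photosensor voltage from `OC/responsivity` with a configured
`V0` (default 0.5 V, the worked-example value). The optical current is
derived by inversion rather than from physical optics: at
child-plausible TBW values the published TBW equation implies optical
currents (and hence voltages) far outside the photosensor's physical
range, another documented inconsistency of the printed chain. The
inverted frames are exact algebraic pre-images, not physically plausible
sensor readings, and the round-trip tests rely only on the former
property. Sampling applies
subject-specific lower bounds on FFM and MM so the implied impedance
and resistance stay positive. Compositions outside the invertible
domain raise an error naming the offending relation.

All randomness flows through a single integer seed
(`withr::with_seed`); no function alters global RNG state, and
identical seeds give byte-identical cohorts.

The virtual device pair (`simulate_device_pair()`) adds independent
zero-mean Gaussian error per device and parameter. It exists to
exercise the agreement statistics end-to-end; it models no systematic
bias, drift or heteroscedasticity, so passing tests demonstrate the
statistics are computed correctly, not that any physical device meets
them.

## Numerical and testing choices

* Equation arithmetic is IEEE double throughout; reported tables round
  to 2 decimals (accuracy) or 3 decimals (means), matching the
  published layout, while all internal math keeps full precision.
* Published values are checked at their printed precision. Two printed
  percent-difference cells are truncations rather than roundings of the
  recomputed values (4.6055 printed as 4.605, 20.2068 as 20.206), so
  agreement is asserted to within 0.001, the printed resolution.
* Monte-Carlo checks use fixed seeds and tolerances derived from
  sampling theory: the 10,000-subject group-mean check allows 4
  standard errors; the limits-of-agreement coverage check at n = 10,000
  uses the [0.94, 0.96] band (about 4.6 binomial SDs around 0.95); the
  stepwise null check runs 200 single-candidate replicates at n = 500 —
  with one candidate the partial-F entry test is exact, so the
  intercept-only probability is the nominal 0.95 — and asserts the
  observed fraction within 3 Monte-Carlo standard errors. With several
  simultaneous noise candidates the family-wise entry probability is
  necessarily above the per-test level (1 - 0.95^k); controlling it is
  a property no unadjusted stepwise procedure has, so it is not
  asserted.
* Problem sizes in the suite (cohorts of 10-10,000, 200 stepwise
  replicates) were chosen so each check's Monte-Carlo error is well
  inside its tolerance; the full suite runs in a few seconds.

## Known limitations

* The generator reproduces marginal summary statistics, not the joint
  distribution of real anthropometry; independence (or a copula toward
  one published correlation matrix) is an explicit modelling
  assumption. Subject-level study results are therefore not
  reproducible here and are carried only as verbatim packaged tables.
* The published equations are reproduced bug-for-bug where they are
  internally inconsistent; this package is a faithful model of the
  device's arithmetic, not a corrected re-derivation.
* No hardware concerns are modelled: no ADC quantization of the
  photosensor voltage, no electrode contact effects, no DFT internals
  of the impedance converter (its output magnitude is consumed).
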