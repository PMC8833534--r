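---
title: "Methods: delineation-based proton-therapy selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delineation-based proton-therapy selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonSelect)
```

## Overview

`protonSelect` predicts, per head-and-neck patient and before any
treatment planning, whether a formal photon-vs-proton plan comparison
is likely to qualify the patient for proton therapy under
model-based selection. The chain is: delineation geometry →
per-organ mean-dose predictions for both modalities → four NTCP
values per modality → ΔNTCP profile → protocol threshold decision.
This vignette documents the model, its assumptions, the tunable
parameters, the synthetic data generator, and the numerical and
design choices, in that order.

## Geometry: overlap features

All geometry operates on binary masks sharing one voxel grid with
physical spacing in mm. For a margin $r \ge 0$ the two targets
(`PTV_7000`, `PTV_5425`) are expanded isotropically *in physical
space*: a voxel belongs to the expanded mask iff its center lies
within Euclidean distance $r$ of the center of some voxel of the
input mask. The distance field is an exact separable squared
Euclidean distance transform (lower-envelope-of-parabolas
algorithm, implemented in C++), with per-axis spacing, so thick CT
slices are handled correctly — a 5 mm margin spans fewer slices
than in-plane pixels. The discretization choice
(voxel-center-to-voxel-center distance, inclusive comparison with a
$10^{-7}\,\mathrm{mm^2}$ squared-distance tolerance against
floating-point dust) makes margin 0 an exact identity and expansion
monotone and inflating by construction.

The two predictors per OAR and margin are volume fractions by voxel
counting (uniform voxel volume, so the grid cancels):

* `pct_in70` — % of the OAR inside the expanded 70 Gy target;
* `pct_in54_out70` — % inside the expanded 54.25 Gy target but
  outside the expanded 70 Gy one.

`PTV_5425` is unioned with `PTV_7000` at load time so the "inside
54.25, outside 70" shell is well defined even when input masks are
exclusive rings. Sub-voxel (polygonal) volume estimation is
deliberately not attempted: voxel counting is the simplest
estimator whose error is controlled by grid resolution, and both
predictors are ratios of counts on the same grid. Masks must be
pre-resampled to a common grid; resampling is out of scope. An
anatomically absent organ (e.g. a resected gland) is carried as an
explicit flag, never as an empty mask, and propagates as `NA`
features.

Expansion is fully 3-D. The margin grid default,
$\{0, 3, 5, 7, 10, 15\}$ mm, covers the physically plausible
penumbra range; nothing in the code restricts margins to this set.

## Dose models

Per OAR $o$ and modality $m$, at margin $r$:

$$D_\mathrm{mean}(o, m) = \beta_0 + \beta_1\,\mathrm{pct\_in70}(o; r)
  + \beta_2\,\mathrm{pct\_in54\_out70}(o; r) + \varepsilon,$$

fitted by ordinary least squares (`stats::lm`). Reported per model:
in-sample $R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$ (the selection
statistic is apparent, not cross-validated — model selection here is
a descriptive "which margin explains the dose best", not a
generalization claim); residual SD with the $n-3$ denominator
(three estimated coefficients); and t-based 95% coefficient
intervals from the standard OLS covariance. The margin with the
highest $R^2$ wins per OAR × modality; ties break toward the
*smallest* margin, the cheapest geometry. Degenerate cells —
fewer than 4 complete patients, collinear predictors, zero-variance
response — are reported as errors (a zero-variance response has no
meaningful $R^2$, so it is neither 0 nor 1), and a failed cell never
aborts the rest of the grid.

Predictions are clamped to $[0, 70]$ Gy: the linear form can go
negative for organs far from both targets and (rarely) above the
70 Gy prescription maximum, neither of which is physical.

### Post-hoc sensitivity adjustments

Because a false negative (missed qualification) costs more than a
false positive in centers prioritizing sensitivity, three
adjustments can bias predictions toward qualification, optionally
restricted to a subset of organs such as the salivary glands:

* `rescale` — multiply predicted IMPT doses by a factor (e.g. 0.85);
* `ci_bound` — re-predict from the lower (IMPT) or upper (VMAT)
  95% bound of *all three* coefficients simultaneously (intercept
  included; applying the bound only to slopes would under-shift
  organs with small overlap);
* `sd_shift` — subtract $k$ residual SDs from predicted IMPT doses,
  floored at 0 Gy. Each model's own residual SD is the default; a
  pooled SD can be supplied instead when a single figure-level
  spread estimate is preferred.

## NTCP and the decision rule

Each endpoint (grade ≥2 / ≥3 dysphagia and xerostomia) is a logistic
model over the eight OAR mean doses plus an additive coefficient for
the patient's baseline complaint level:

$$\mathrm{NTCP} = \operatorname{logit}^{-1}\Big(\beta_0 +
  \textstyle\sum_o \beta_o D_\mathrm{mean}(o) +
  \beta_\mathrm{baseline}\Big).$$

Coefficients are *configuration*, not code: clinical protocol
coefficients are loaded from JSON/YAML (`readNtcpModels()`), and the
package ships only a synthetic, clearly-labelled fixture set. The
ΔNTCP profile is $100\,(\mathrm{NTCP_{VMAT}} -
\mathrm{NTCP_{IMPT}})$ per endpoint, in percentage points; negative
values (proton worse) are preserved, never clipped — they simply
cannot satisfy any criterion.

The qualification rule (defaults in `thresholdConfig()`): a single
grade ≥2 gain ≥ 10 pp; a single grade ≥3 gain ≥ 5 pp; a grade ≥2
sum ≥ 15 pp; a grade ≥3 sum ≥ 5 pp. All comparisons are inclusive
(≥). For the sum criteria, the per-endpoint minimum (5 pp for
grade ≥2, 3.75 pp for grade ≥3) is read as a *contribution filter*:
an endpoint below its minimum is excluded from the sum rather than
voiding the criterion. With only two endpoints per grade the
alternative reading — both endpoints must pass the minimum before
the sum is evaluated at all — differs only on profiles where one
endpoint alone already exceeds the sum threshold, and for grade ≥3
that case is already covered by the single-endpoint criterion; the
contribution-filter reading keeps the grade ≥3 sum criterion
non-vacuous, which is why it was chosen. Protocol summaries
sometimes state the two single-endpoint thresholds in the opposite
order; the detailed enumeration (10 for grade ≥2, 5 for grade ≥3)
is authoritative here.

In hybrid comparison mode the VMAT side of the profile comes from an
actual VMAT plan's doses while IMPT stays predicted — useful because
photon dose prediction, not proton, dominates the error budget.
Missing organs are a hard error by default; an explicit opt-in
imputes 0 Gy with an audit warning (a truly absent organ receives no
dose and contributes no toxicity risk through its dose term).

## Evaluation

Predicted decisions are scored against actual plan-comparison
decisions with "qualifies" as the positive class: sensitivity,
specificity, PPV, NPV and accuracy, each with a 95% CI — Wilson
score by default (well-behaved near 0 and 1), exact Clopper–Pearson
by flag. A measure with a zero denominator is reported as
undefined, not 0. Subgroup robustness mirrors clinical practice:
a learning-curve split (first half vs second half by treatment start
order, the extra patient going to the second half) and tumor
location; subgroup estimates are flagged when they leave the
whole-cohort CI of the same measure. Predicted-vs-actual agreement
for continuous quantities (doses, NTCPs) is summarized as the
squared Pearson correlation (the scatter-plot sense of $R^2$;
a regression flavor is available by flag) plus the mean and SD of
residuals, with `predicted − actual` as the sign convention.

## Synthetic data

Two tiers share one generative dose model.

**Voxel phantoms** (`phantomSpec()`, `generatePhantom()`) rasterize
axis-aligned ellipsoids by the voxel-center-inside rule, giving
exact, reproducible geometry with analytic volume oracles. They
exercise the full mask pipeline at small $n$.

**Feature-level cohorts** (`cohortSpec()`, `generateCohort()`) skip
voxels entirely for statistical work at realistic cohort sizes. Per
patient and OAR, a latent proximity $d_{70}$ (mm) and target-level
gap are drawn, and overlap percentages follow logistic-in-margin
profiles — monotone in margin with totals ≤ 100 by construction.
Actual doses are the true linear model at that modality's true
margin plus homoscedastic Gaussian noise, clamped to $[0, 70]$ Gy;
actual qualification labels come from running the NTCP models and
thresholds on those actual doses. Random numbers are consumed in a
fixed documented order (see `?cohortSpec`), so a seed fully
determines the cohort and seeds are portable across versions.

Defaults were chosen once to emulate a national-selection cohort
year: $n = 151$; true margins around 10 mm (VMAT) and 5–7 mm (IMPT);
photon models with a sizable out-of-field bath intercept (8–14 Gy)
and slopes 0.55 / 0.30 Gy per %, proton models with a 2 Gy intercept
and steeper slopes 0.65 / 0.32 (dose concentrated at the target);
residual noise 3 Gy (VMAT) and 2 Gy (IMPT), reflecting the tighter
proton dose–overlap relation; and synthetic NTCP coefficients whose
magnitudes were calibrated so that roughly 70% of simulated patients
qualify — the prevalence regime the selection procedure operates in.
The test suite checks the realized fraction against a 0.60–0.80 band
at $n = 500$.

What the generator does *not* emulate — and hence what passing tests
cannot show about clinical data: real delineation variability and
anatomy (ellipsoids, not organs); planning-system behavior (the true
dose model is exactly linear, so noiseless recovery is exact by
construction, which is the point of those tests, not evidence about
planning data); heteroscedastic or skewed dose residuals; and
correlations between baseline complaints, tumor location and
geometry. Clinical deployment requires refitting all dose models on
local planning data and supplying the protocol NTCP coefficients.

## Numerical choices and degenerate inputs

* Expansion: inclusive distance comparison with
  $10^{-7}\,\mathrm{mm^2}$ absolute tolerance on squared distances;
  margin 0 returns the input object unchanged.
* OLS: `stats::lm` (QR); singular designs are errors naming the
  OAR/margin cell, not silent `NA` coefficients.
* Margin ties: smallest margin wins, deterministically.
* Dose clamping to $[0, 70]$ Gy in prediction, adjustment and
  simulation.
* `decide()` requires all four endpoints and rejects `NA` deltas;
  the batch path (`decideBatch()`) is the same rule vectorized and
  is tested for exact agreement against a brute-force evaluator on
  a dense 4-D profile grid.
* CSV output from the CLI is written at 6 significant digits so
  repeated runs are byte-identical; JSON model stores keep full
  precision.

## Problem sizes in the test suite

Oracle-equivalence tests for mask expansion use grids up to
$15^3$ voxels, where the all-pairs distance computation is exact and
fast; decision-rule equivalence enumerates the full
$\{0, 0.5, \dots, 25\}^4$ profile grid (6.8M profiles) vectorized;
parameter-recovery and coverage tests use cohorts of $n = 151$ with
200 replicates for the 95% CI coverage check (binomial tolerance
band 0.89–0.995). These sizes keep the whole suite in the
low-minute range on one core while leaving each property
sharply falsifiable.

## Known limitations

* Single-center, two-dose-level assumptions are baked into the
  feature definition (two nested targets at 70 / 54.25 Gy);
  other fractionation schemes need new features and refits.
* Apparent (in-sample) $R^2$ drives margin selection; with 6
  candidate margins overfitting pressure is mild, but the selected
  margin is not a validated optimum.
* The NTCP stage trusts its configuration: no refitting,
  recalibration or endpoint extension is provided.
* Masks must share a grid; no resampling, registration or DICOM-RT
  handling.
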