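---
title: "Methods: quantitative lower-leg muscle features for PAD severity"
author: "muscleCTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative lower-leg muscle features for PAD severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleCTA)
```

## The scientific problem

Peripheral arterial disease (PAD) narrows or occludes the lower-leg
arteries.  Severity is graded on digital subtraction angiography (DSA)
with a modified Society for Vascular Surgery runoff score (0–19, higher
is worse), dichotomised into *mild* (score ≤ 7) and *severe* (> 7)
disease.  Chronic hypoperfusion changes the muscle itself — lower mean
attenuation, more intramuscular fat, more heterogeneous texture — so
quantitative muscle features measured on routine CT angiography (CTA)
carry information about the vascular status without grading the vessels
directly.

The package implements that analysis chain as reusable components:

1. **Segmentation** of lower-leg muscle by an inclusive HU window
   (−10 to 100 HU) followed by structural cleanup of bone marrow and
   veins (`thresholdSegment()`, `cleanMask()`, `restrictZ()`).
2. **Feature extraction**: 20 histogram features and 75 gray-level
   texture features (24 GLCM, 14 GLDM, 16 GLRLM, 16 GLSZM, 5 NGTDM),
   plus 2 conventional and 14 radiomic shape features (`extractAll()`).
3. **Screening**: z-score standardisation and univariable tests at
   p < 0.05 (`zscore()`, `screenFeatures()`).
4. **Modelling**: LASSO selection with ten-fold cross-validation,
   logistic regression with Wald odds ratios, likelihood-ratio omnibus
   and Hosmer–Lemeshow diagnostics, ROC with DeLong intervals and a
   Youden-index cutoff (`lassoSelect()`, `fitLogistic()`,
   `rocAnalysis()`, `buildModels()`).
5. **Published predictors**: the fixed-coefficient models LRM-I
   (`logit(P) = −1.29·f1 − 0.67·f2 − 0.85`, cutoff 0.35) and LRM-II
   (`logit(P) = 1.18·CTA − 1.11·f1 − 0.68·f2 − 0.90`, cutoff 0.43) on
   z-scored inputs, where `f1 = histogram_10Percentile` and
   `f2 = gldm_DependenceNonUniformityNormalized`
   (`predictPublished()`).
6. **Sub-dataset analysis**: the segmentation region is divided into
   five equal knee→ankle segments and the models are re-evaluated on
   features from each segment alone, with the whole-leg standardisation
   parameters and the fixed whole-leg cutoffs (`splitZ()`,
   `evaluateSubsets()`).

No patient data are distributed or downloadable; a synthetic phantom
module (`generatePhantom()`, `generateCohort()`) supplies inputs with
the statistical structure the analysis assumes, so every stage is
testable.

## The phantom: what it emulates, and what it does not

The phantom is a stylised two-bone lower leg on a 64 × 64 × 60 grid at
3 × 3 × 5 mm spacing (a leg covered by 60 axial CTA slices): an
elliptical subcutaneous fat ring, a muscle compartment filling the
interior, tibia and fibula analogues (cortical shell around a marrow
core), three contrast-filled arteries inside the muscle, and two
subcutaneous veins.  Geometry scales with the grid; structures that end
up with no voxels on coarse grids raise an error naming the structure.

Only HU composition and structural adjacency are meant to be realistic:

* **Muscle**: voxels are drawn i.i.d. from N(44.6, 16.0²) HU for mild
  and N(39.5, 16.7²) HU for severe subjects — the group-level means and
  SDs of the reference cohort.  A configurable fraction (default 2%) of
  muscle voxels is replaced by intramuscular-fat speckle at −80 HU,
  mimicking the fat infiltration the original segmentation could not
  fully exclude.
* **Interference tissues**: marrow (30 ± 10 HU) and veins (90 ± 10 HU)
  sit *inside* the muscle threshold window, so a correct segmentation
  must remove them structurally; fat (−100 HU), cortical bone
  (1000 HU) and contrast arteries (300 HU) fall outside the window.
* **Severity gradient along the leg**: severe subjects receive a distal
  HU offset (default −4 HU at its peak).  The offset profile rises
  quadratically from the knee, peaks at 70% of the knee→ankle axis and
  falls linearly to 30% at the ankle.  This models ischemia that is
  most expressed in the distal calf muscle territory rather than at the
  ankle, where the compartment is mostly tendon; it is a modelling
  choice of this package, not a measured profile.  A strictly linear
  ramp is available via `distalProfile = "linear"`.
* **Between-subject variability** is applied at cohort level only:
  `generateCohort()` jitters each subject's muscle mean by N(0, 4 HU)
  and the muscle SD by N(0, 0.6 HU) around the group parameters.  The 4
  and 0.6 HU defaults were read off the spread of the reported group
  summaries (the interquartile ranges of the mean and SD rows of the
  univariable table).  `generatePhantom()` itself stays exactly on the
  configured parameters so that distributional fidelity is testable.
* **Runoff scores**: DSA scores are drawn from group-conditional
  normals (mild 3.3 ± 2.6, severe 12.3 ± 3.0), clipped to [0, 19] and
  resampled until consistent with the dichotomisation boundary; CTA
  scores are generated conditionally on the DSA score with latent
  correlation 0.8 (a free parameter) and the reported group CTA
  summaries (6.1 ± 4.0 / 11.8 ± 5.1).

The phantom does **not** emulate: partial-volume mixing at tissue
boundaries, anatomic muscle compartments or per-muscle boundaries,
vessel trees or contrast-bolus dynamics, beam hardening or other
reconstruction artefacts, slice-to-slice anatomy changes (taper), or
correlated (textured) muscle signal — muscle voxels are independent
given the subject parameters.  Passing tests therefore demonstrate that
the *pipeline* recovers the statistical structure it assumes, not that
it would perform identically on patient images.

## Segmentation rules replacing manual correction

The reference workflow corrected the threshold mask manually.  Here the
correction is two deterministic rules, which is the package's largest
deliberate deviation:

* **Marrow**: per slice, any in-window voxel that cannot be reached
  from the slice border through voxels below 300 HU (the cortical-bone
  detector) is removed — a flood-fill formulation of "enclosed by
  bone".  The flood uses 4-connectivity, so a cortical ring that is
  closed under 8-connectivity cannot leak diagonally.
* **Veins and noise**: 3D 26-connected components smaller than
  `minComponentVoxels` (default 27, a 3×3×3 speckle) are removed; then,
  per slice, only the largest 8-connected component and components at
  least 10% of its size are retained.  Subcutaneous vein cross-sections
  are far below 10% of the muscle cross-section, so they are removed
  regardless of their 3D tube length.

Both HU bounds are inclusive; this is asserted explicitly in the tests
(voxels at −10 and 100 HU are in, −11 and 101 are out).

## Feature definitions and numerical choices

Feature definitions follow the IBSI/pyradiomics conventions — the
family counts (20/24/14/16/16/5) match that bank exactly.  The choices
the reference leaves open are fixed as follows:

* **Discretisation**: fixed bin width of 5 HU anchored at the ROI
  minimum (`level = floor((x − min)/w) + 1`); gray levels are bin
  indices.  Texture is computed in 3D over the whole ROI with the 13
  unique distance-1 directions and 26-voxel neighbourhoods;
  direction-wise matrices (GLCM, GLRLM) give one feature value per
  direction, averaged afterwards.  A 2D in-plane mode (matrices pooled
  over slices) is available via `discretizationParams(mode = "2d")`.
* **Moments**: population (n) denominators; kurtosis is non-excess
  (Pearson) — the reported kurtosis values cluster near 3.8, which is
  impossible under the excess convention.  Percentiles interpolate
  linearly between order statistics (R's default type 7).
* **Degenerate inputs**: at zero variance, skewness and kurtosis are 0,
  GLCM Correlation and MCC are 1, Imc1/Imc2 are 0; at zero mean, CV is
  reported as `NaN` with a warning rather than an error.  Entropies sum
  over positive-probability cells only, so a constant ROI has entropy
  exactly 0.  Energy is computed without any intensity shift.
* **GLDM**: a neighbour is dependent iff its level differs by at most
  α = 0; the recorded dependence is the neighbour count, and feature
  weights use count + 1 (a voxel depends on itself), keeping every
  feature finite for isolated voxels.
* **Shape**: the surface is the set of exposed voxel faces, and the
  mesh volume follows from that axis-aligned boundary by the divergence
  theorem (hence it equals voxel count × voxel volume); sphericity uses
  the classic `π^(1/3)·(6V)^(2/3)/A`.  Maximum diameters are the
  largest pairwise distances between boundary-voxel centres (in-plane
  for the 2D variants); axis lengths are `4·sqrt(λ)` from the
  covariance of the physical voxel coordinates.
* **Mode** (histogram): centre of the most populated bin, ties resolved
  toward the lowest bin.

Every texture feature is verified against an independent brute-force
enumerator (explicit pair/run/zone enumeration in plain R) on random
ROIs at tolerance 1e−9 in the test suite.

## Statistical stages

* **Screening** uses Student's equal-variance t test when both groups
  pass Shapiro–Wilk at α = 0.05, otherwise the Mann–Whitney U test
  (normal approximation with tie correction); Welch's t is available as
  an option.  No multiple-testing correction is applied — screening at
  p < 0.05 is the reference analysis's own convention, kept
  deliberately.  Categorical tables use Pearson's chi-squared without
  continuity correction, switching to Fisher's exact test for 2×2
  tables with an expected count below 5.
* **LASSO** minimises squared error on the 0/1 outcome (the MSE
  criterion of the reference's cross-validation figure), solved by
  coordinate descent (glmnet) on the pre-standardised matrix over a
  log-spaced λ grid, with outcome-stratified ten-fold cross-validation;
  λ* is the minimum-MSE value, not the 1-SE rule.  A logistic-deviance
  LASSO is available behind `loss = "deviance"`.
* **Post-selection pruning**: the reference's coefficient table marks
  some LASSO-selected variables "not reported", implying a second
  selection step.  `buildModels()` offers an interpretation of it —
  backward elimination on Wald p-values, retaining variables with
  p < 0.10 (the reported LRM-II kept a variable at p = 0.06), never
  dropping the CTA score from LRM-II — behind `refine = "backward"`.
  The default is `refine = "none"`: LRM-II then uses exactly LRM-I's
  features plus the CTA score, so the two models are nested, which is
  what the module contract states and what makes the expected
  AUC ordering (LRM-II at least as discriminative in-sample) a
  structural property rather than a tendency.
* **Diagnostics**: the omnibus test is the likelihood-ratio test
  against the intercept-only model; Hosmer–Lemeshow uses 10 groups by
  predicted-probability deciles with ties split by stable sort; odds
  ratio intervals are `exp(coef ± 1.96·SE)`.
* **ROC**: the AUC is the Mann–Whitney probability (ties count 1/2);
  its confidence interval and the test against 0.5 use DeLong's
  variance (via pROC).  The reported cutoff maximises the Youden index
  over midpoints between consecutive observed scores, with ties broken
  toward the lower (more sensitive) cutoff; a subject is called severe
  when its score is at or above the cutoff.  Perfect separation in a
  logistic fit is detected (deviance ≈ 0) and raised as an error with a
  hint toward penalisation; the pipeline downgrades it to a warning so
  smoke-scale runs complete.
* **Sub-dataset evaluation** standardises per-segment features with the
  *whole-leg* transform parameters (re-standardising per segment would
  leak information) and never re-optimises cutoffs per segment.
  Remainder slices of the equal partition go to the proximal segments.
  Subjects with an empty segment mask are excluded from that segment
  with a warning.
* **ICC** for reader agreement is the two-way random-effects,
  absolute-agreement, single-rater ICC(2,1) with the F-based interval;
  the reference does not state the variant.

## Problem sizes used by the test suite

The simulation-based checks run at the study conditions: cohorts of 36
mild and 20 severe subjects on 64 × 64 × 60 grids, 50 seeded replicates
for the cohort-level properties (screening direction, model ordering,
sub-dataset peak), 1000 replicates for the univariable type-I error,
and 100 seeded runs for LASSO selection consistency.  Unit tests use
48 × 48 × 16 phantoms.  All randomness is seeded; identical seeds give
byte-identical cohorts, models and output tables.

## Known limitations

* The runoff rubric's exact segment table and weights are not public;
  the default (six segments graded 0–3 plus a pedal arch graded 0–1) is
  an assumption constrained by the printed 0–19 range and is fully
  configurable.
* The reference's exact discretisation, 2D/3D aggregation and distance
  settings are unknown; the defaults above are this package's choices.
* Reproducing the reference's patient-level numbers (AUC 0.81/0.84/0.89,
  the 45 screened features, λ = 0.044) requires the unavailable patient
  data and is out of scope; the phantom-based checks validate the
  machinery, directions of effects, and orderings instead.
* The phantom's i.i.d. muscle signal makes texture features less
  variable than in real tissue; absolute texture values should not be
  compared against patient studies.
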