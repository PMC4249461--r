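---
title: "Decoding cardiovascular risk from gray-matter images: methods and design"
author: "cvdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding cardiovascular risk from gray-matter images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdecode)
```

## The problem

Cardiovascular risk factors — hypertension, diabetes, dyslipidemia,
smoking — are associated with gray-matter (GM) loss in otherwise healthy
elderly people, in regions that overlap the Alzheimer-typical temporal
and parietal cortices. Composite risk indices such as the Framingham
coronary heart disease risk (FCHDR) score summarize these factors into a
single gender-specific integer. `cvdecode` asks the multivariate
question: do spatially distributed GM patterns carry enough information
to predict an individual's cardiovascular risk, and does that
information survive control for the major shared genetic risk factor,
the APOE epsilon-4 allele?

The package implements the full decoding battery: binary risk-group
classification with a kernel SVM, support vector regression (SVR) of the
continuous score and of single risk factors, kernel-level confound
removal, matched cross-validation, permutation inference, and voxel
weight-map back-projection — together with a synthetic cohort generator
that makes every stage testable without clinical data.

## Models and procedures

### Features, mask, kernel

Inputs are per-subject 3-D GM probability maps (voxel values in [0, 1],
segmentation/normalization/smoothing done upstream) plus a clinical
table. Voxels whose GM probability falls below 0.15 are discarded;
because a shared feature space needs one common mask, the default keeps
voxels whose *across-subject mean* reaches the threshold
(`rule = "mean"`), with a stricter every-subject variant
(`rule = "all"`) available. Voxels exactly at 0.15 are kept. Masked
voxels are flattened to a subject-by-voxel matrix and combined into a
linear kernel \(K = XX'\). The kernel family is linear throughout: with
far fewer subjects than voxels nothing more flexible is identifiable,
and only a linear model back-projects to an interpretable voxel weight
map.

### Confound removal on the kernel

APOE4 carrier status (plus an intercept) forms the confound design
\(C\); the residual-forming projector
\(R = I - C(C'C)^{-}C'\) (rank-tolerant pseudoinverse) is applied as
\(RKR\), which equals the Gram matrix of the residualized features
\(RX\). The intercept is always included so removal also centers the
kernel. Removal is computed on the full sample by default, matching the
practice of applying one residual matrix to "the kernels". This mixes a
small amount of test information into the kernel; a train-only variant
(`removeConfoundsFold()`, or the `confounds =` argument of the CV
engines) estimates the confound regression on each fold's training
subjects and residualizes the held-out kernel blocks with the
train-estimated coefficients. The distinction matters most in the
degenerate but diagnostic case where the prediction target *is* the
confound: full-sample removal then anti-learns (cross-validated
accuracy driven far below chance, r towards −1), because the in-sample
orthogonality constraint couples held-out predictions negatively to the
target, whereas the fold-wise variant sits at chance as it should. Only
*linear* confound dependence is removed in either variant: if a
confound modulates the images through an interaction (as the
generator's APOE-by-score term does), that component is outside the
span of \(C\) and legitimately survives removal.

After removal the kernel is scaled to unit mean diagonal
(`normalizeKernel()`). This trace normalization puts the Gram matrix on
a scale commensurate with the fixed soft-margin cost; without it the
behavior of \(C = 1\) depends on arbitrary units of the feature inner
products, which we found destabilizes leave-one-out SVR across
simulated cohorts (correlations swinging from 0.3 to 0.9 at identical
signal strength, stabilizing to 0.73–0.93 once normalized).

### Classification and regression

Binary risk-group classification uses the soft-margin SVM dual on the
precomputed kernel (solved by libsvm via e1071; internally the kernel is
embedded exactly through its eigendecomposition, which leaves the dual
problem unchanged). The lower-risk class is labeled −1 and the
higher-risk class +1; a decision value of exactly 0 predicts +1
(deterministic tie-break). Cross-validation is leave-pair-out: risk
groups are first matched on gender and age (greedy nearest-age within
gender, subject-id tie-break, default caliper 2 years), then each fold
holds out one matched pair so every training set stays balanced.
Accuracy, sensitivity (recall of the higher-risk class) and specificity
(recall of the lower-risk class) are reported, along with the Pearson
correlation between cross-validated decision values ("projections") and
the FCHDR score — computed both over all subjects and over the correctly
classified subset, since either convention is defensible and they
differ.

Regression replaces the categorical target with the clinical measure
itself: epsilon-insensitive SVR under leave-one-out CV. Every target
(including FCHDR) is z-normalized — mean subtracted, divided by the
sample SD — so mean squared errors are comparable across factors
measured in different units; on that scale the trivial mean predictor
has MSE \((n-1)/n \approx 1\), so any MSE materially below 1 indicates
predictive signal. Normalization uses the full sample by default (needed
for cross-factor MSE comparability); a fold-wise option quantifies the
leakage, which is negligible in practice. The single-factor battery
covers FCHDR, averaged systolic blood pressure (mean of the second and
third readings; the first is an acclimatization measurement and is
discarded), age, total and LDL cholesterol, and smoking status, each
within a subgroup (all, female, male, APOE4 carriers, matched
non-carriers), with the confound design rebuilt and re-applied inside
the subgroup. Diabetes, being dichotomous (fasting glucose ≥ 126 mg/dl
and/or hypoglycemic medication), is handled by leave-one-out
classification against the majority-class rate.

### Permutation inference

Significance comes from permutation tests that re-run the complete
cross-validated pipeline on shuffled targets; the kernel, confound
design and fold structure stay fixed. p equals the exact proportion of
permuted statistics at or beyond the observed one (upper tail for
accuracy and correlation, lower tail for MSE); a zero count is reported
as "≤ 1/B", and an add-one correction is available behind a flag. For
*paired* classification designs, labels are exchanged within matched
pairs rather than globally: a global shuffle breaks the one-per-class
pair structure that the observed statistic always has, and in a
calibration experiment (100 null cohorts) it pushed the type-I error
just above its binomial tolerance, while within-pair swapping is the
exchangeability-respecting null for a matched design. Unpaired
regression targets are shuffled globally (a within-gender stratified
option exists).

### Weight maps

The primal weight vector is recovered from the dual coefficients in the
residualized feature space, \(w = (RX)'c\) (divided by the square root
of the kernel scale when the kernel was trace-normalized), because the
model was trained on \(RKR\); mapping back through raw features would
misstate the pattern. Maps are exported raw or unit-normalized, as NIfTI
with a JSON sidecar. Positive weights associate higher GM with a higher
predicted score. The weights form one global multivariate pattern —
every voxel contributes jointly — so regional or single-voxel inference
from a weight map is not appropriate, and the sidecar says so.

## The synthetic cohort generator

`generateCohort()` emulates the statistical structure the analysis
assumes, not neuroanatomy:

* ages integer-uniform on 66–75; gender Bernoulli (56% female); APOE4
  Bernoulli (22% prevalence), mirroring the demographic marginals the
  pipeline targets;
* integer FCHDR scores from gender-specific normals (males ≈ N(6.5, 3),
  females ≈ N(11.5, 3.5), rounded, clipped at 0), chosen so the
  gender-specific cutoffs (male 5/8, female 9/14) populate all three
  risk groups from n ≈ 30;
* single factors (glucose + medication flag, three systolic readings
  with an elevated first measurement, total/HDL/LDL cholesterol,
  smoking) drawn in plausible adult ranges with mild positive coupling
  to the standardized score;
* images: a smooth baseline template (center ≈ 0.8, falling below the
  0.15 mask threshold at the corners) minus
  `slope(gender) × (1 + apoeEffectMultiplier × APOE4) × z × pattern`
  plus spatially smooth noise, clipped to [0, 1]. The signal direction
  is GM *loss* with rising risk. The pattern occupies
  `patternSparsity` of the voxels in contiguous blobs; smoothness is a
  Gaussian blur (FWHM ≈ 2 voxels) emulating 8 mm FWHM smoothing at toy
  scale, with the noise field rescaled after blurring so `noiseSd` stays
  the marginal SD.

Gender differences are encoded as separate slopes with male slope 0 by
default, reproducing the qualitative finding that the image-risk
coupling is expressed in females and absent in males; APOE4 modulates
the slope multiplicatively (default ×1.5 in carriers).

No effect-size estimate for the GM-risk association exists to copy, so
the slope is a free parameter. It was fixed once by an upfront pilot:
with `noiseSd = 0.05`, a female slope of 0.05 GM-units per score SD
yields leave-one-out SVR correlations of 0.73–0.93 (mean ≈ 0.86) in
120-subject female cohorts — a strong but unsaturated signal, the regime
the recovery checks are meant to probe — and that value is frozen as the
default. What passing tests show is therefore that the *pipeline*
recovers a planted, linear, spatially smooth signal at realistic sample
sizes; real cohorts add registration error, nonlinear and
heteroscedastic effects, and far higher-dimensional masks, none of
which the generator emulates.

## Numerical choices and degenerate inputs

* SVM/SVR hyperparameters are deliberately fixed (C = 1, epsilon = 0.1,
  solver tolerance 1e-4), configurable but untuned — no inner
  model-selection loop.
* The SVM solver is libsvm through e1071 on an exact eigendecomposition
  embedding of the kernel (\(ZZ' = K\), negative eigenvalues clipped at
  0); the dual depends on the kernel only, and decision values for new
  subjects are computed from kernel blocks against the training sample.
* `residualMatrix()` uses a pseudoinverse, so rank-deficient confound
  designs (duplicated columns, constant covariates) are handled; the
  factor battery drops confounds that are constant within a subgroup
  (for example APOE4 inside the carriers-only split).
* Degenerate targets (constant vectors) raise errors at z-normalization
  rather than producing silent NaNs; empty denominators in
  sensitivity/specificity yield `NA` markers, not exceptions.
* Matching is greedy with deterministic (subject-id) tie-breaks:
  reproducible and adequate at cohort scale, though not guaranteed
  maximum-cardinality under a finite caliper.
* All generators and permutation engines take explicit integer seeds and
  restore the caller's RNG state; identical configuration and seed give
  bit-identical output.

## Validation scales

The test suite exercises the statistical claims at desk scale, chosen to
keep a complete run within minutes while leaving the checks
well-powered: null-mean calibration on one 60-subject cohort with 200
permutations; type-I error over 100 null cohorts of 20 subjects at
B = 99; signal recovery on a 120-subject female cohort (B = 199); the
gender battery over ten 60-subject cohorts at B = 49. The acceptance
script re-runs the null-mean calibration from scratch at n = 60,
B = 200.

## Known limitations

* Full-sample confound removal and full-sample target normalization leak
  a small amount of test information by construction; both have
  stricter variants behind flags.
* Only linear confound effects are removed; interactions with the
  confound survive (by design of the residual projector).
* The matched-pair counts of a real cohort depend on the exact matching
  procedure and caliper; greedy matching reproduces the qualitative
  behavior (pair counts at or below within-gender minima), not any
  specific published pair count.
* No multiple-testing correction is applied across the factor battery;
  the battery mirrors a descriptive table, and readers should treat the
  per-factor p-values accordingly.
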