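---
title: "Methods: longitudinal FDG-PET features for MCI conversion prediction"
author: "petmci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal FDG-PET features for MCI conversion prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Mild cognitive impairment converts to Alzheimer's disease in roughly 10-15%
of patients per year. Given four FDG-PET sessions per patient (baseline and
6, 12, 18 months) plus MMSE and ADAS-cog scores, the task is a binary
classification: progressive (pMCI, the positive class) versus stable
(sMCI). The package's premise is that the *trajectory* of regional glucose
metabolism carries information that a single baseline scan does not, and it
therefore compares three feature families under one common protocol:

1. **Static**: per-region mean normalized intensity $T$ at each timepoint.
2. **Dynamic**: per region, the difference from baseline
   $D_i = T_{baseline} - T_i$ and the change rate
   $R_i = D_i / T_{baseline}$ for follow-up $i = 1, 2, 3$
   (months 6, 12, 18). $D$ and $R$ carry the same sign information but
   different scaling; both are exposed as separate blocks, and the
   combined "Dynamic_all" configuration is the three $D$ blocks
   (`standardFeatureCombinations(includeRates = TRUE)` adds $R_{1..3}$).
3. **Cognitive**: the eight raw scores (MMSE and ADAS-cog at four
   timepoints).

Classification is a soft-margin SVM with RBF kernel
$K(x_1, x_2) = \exp(-\|x_1-x_2\|^2 / 2\sigma^2)$, evaluated by
leave-one-out cross-validation in which *everything subject-dependent* —
the F-score ranking, the top-$k$ choice, the z-scaling — is refit on the
$n-1$ training subjects of each fold.

# Intensity normalization

Global-mean scaling alone biases group comparisons: a globally
hypometabolic patient is scaled *up*, which dilutes regional disease
effects. The two-step reference-cluster procedure addresses this. After
global-mean scaling, a voxel-wise two-sample t-test contrasts patients
with healthy controls; voxels with higher patient mean at one-sided
$p < \alpha$ form the reference cluster — in a declining brain these are
the relatively preserved voxels — and images are rescaled by their mean
over that cluster.

Decisions the procedure's published description leaves open, and the
choices made here:

- **Sidedness.** "Hypermetabolic in patients" is a directional statement,
  so the test is one-sided (patient > control). A two-sided test would
  also admit hypometabolic voxels into the reference, contradicting the
  rationale.
- **Variance model.** Pooled (equal-variance) t by default — the classical
  voxel-mapping convention — with `varEqual = FALSE` for Welch.
- **Per-timepoint clusters.** The cluster is recomputed for each timepoint
  from that timepoint's patient images against the healthy-control
  baseline set (`perTimepoint = FALSE` shares the baseline cluster). HC
  subjects contribute baseline images only, since the contrast needs only
  a control reference distribution.
- **No multiplicity correction, no extent threshold.** Selection is the
  plain per-voxel $p < 0.05$ rule; a `minClusterSize` guard exists but
  defaults to off.
- **Empty cluster.** An explicit error instructing the user to fall back
  to global-mean normalization deliberately; a silent substitution would
  change the method under the user's feet.

Two properties pin the implementation down numerically: the full feature
pipeline is invariant to rescaling any raw image by $c > 0$ (both
normalization steps are ratios), and on null data the selected fraction
matches $\alpha$ to Monte-Carlo error (the pooled t is exact under
normality).

# Feature extraction and confound removal

Voxels are averaged within integer-labelled atlas regions (any label
volume on the image grid is accepted; 246 regions mirrors a
Brainnetome-style parcellation). Age and gender effects are removed by
least-squares regression against (intercept, age, gender).

Ordering matters in two ways:

- Voxel-level and region-level residualization are interchangeable for any
  feature *linear* in the voxel data (residuals are linear in the response
  with a shared design; parcellation is an average). The package tests
  this equivalence numerically and uses the cheaper region-level path in
  `runPipeline()`.
- Residuals are mean-zero by construction, so the ratio
  $R_i = D_i/T_{baseline}$ must be computed **before** residualization —
  dividing by a residualized baseline (values near 0) would be numerically
  meaningless. `extractFeatures()` therefore computes $T$, $D$, $R$ from
  the normalized statics first and then residualizes each imaging block;
  for $T$ and $D$ this is exactly equivalent to the voxel-level order.

Cognitive scores are **not** residualized: the published order of
operations applies the regression to image voxels, and cognitive scores
are clinical endpoints in their own right. This is an assumption, exposed
by keeping `residualizeConfounds()` usable on any matrix.

The guard `eps = 1e-12` on $|T_{baseline}|$ makes the undefined-ratio
contract explicit; after normalization intensities sit near 1, so it never
triggers on sane input.

# Feature selection

The F-score of feature $i$ is the squared deviation of the two class
means from the overall mean divided by the sum of the within-class sample
variances ($n_\pm - 1$ denominators). Conventions fixed here:

- The overall mean $\bar x_i$ is the mean over *all* samples (the plain
  reading of the formula), not the mean of the two class means; with
  46/33 class sizes the two differ.
- Ties in $F$ break by ascending original feature index, which makes
  `selectTopK()` deterministic and nested: the top-$k$ set is always a
  prefix of the top-$(k+1)$ set.
- Degenerate zero-variance features (possible for integer cognitive
  scores): $F = 0$ when the class means also coincide; infinite and
  *flagged* (slot `flagged`) when they differ, rather than silently
  dropped.
- Selection is count-based ($k$ features), matching the 1..246 sweep
  design; an F-value threshold is the same operation through the ranking.

# Classification protocol

- **Hyperparameters.** $C = 1$ and $\gamma = 1/p$ (the libsvm defaults)
  unless set; `svmConfig(sigma = )` accepts the kernel width
  parameterisation ($\gamma = 1/2\sigma^2$). No inner tuning loop exists
  by default, because none is part of the protocol being mirrored.
- **Scaling.** Per-fold z-scoring is on by default — standard practice for
  RBF kernels whose distance mixes feature scales — and can be disabled.
- **Positive class.** pMCI, fixed; sensitivity is the pMCI detection rate.
- **ROC/AUC.** Pooled held-out decision values across the $n$ LOO folds
  (the only way a single LOO ROC exists); the curve sweeps every distinct
  score as a threshold and the trapezoidal integral equals the
  Mann-Whitney statistic with ties counted 1/2 — the test suite checks
  this identity against an independent pairwise-concordance loop.
- **Feature-count sweep.** `sweepFeatureCount()` reports the full metric
  curve and the accuracy argmax over $k$ (smallest $k$ on ties). That
  argmax uses pooled test-fold performance and is optimistic; the
  leakage-safe alternative `looEvaluateNestedK()` picks each fold's $k$ by
  an inner LOO on its training set. Both are first-class and labelled.
- Percent metrics are rounded only at reporting time, never internally.

# The synthetic cohort generator

Real longitudinal PET cohorts are access-controlled, so the package ships
a generator that reproduces the *statistical structure* the analysis
relies on, with known ground truth:

- Two MCI groups (default 46 sMCI, 33 pMCI) with multiplicative regional
  decline per timepoint — 5%/tp (pMCI) vs 1%/tp (sMCI) in 25 affected
  regions — plus a 2%/tp background decline in every non-reference region
  of patients. The 20 *reference* regions are left undeclined: after
  global-mean scaling they appear relatively hypermetabolic, exactly the
  signal the Yakushev step searches for. `baselineOffsetPmci` optionally
  plants a cross-sectional (baseline-level) difference instead.
- A healthy-control set (default 40, baseline only) for the normalization
  contrast.
- Additive covariate effects (−0.2 intensity/year of age, +2 for male)
  and i.i.d. Gaussian voxel noise (SD 5 on a baseline mean of 100) on a
  12×12×12 grid partitioned into 246 contiguous serpentine parcels.
  Ages are uniform on 55–85 and gender is Bernoulli(0.7 male), matching
  the demographic ranges of the clinical cohort this emulates; cognitive
  trajectories use the published baseline means/SDs with group-dependent
  drifts and a per-subject random slope, so a subject's four scores are
  correlated.
- Identical seed ⇒ bit-identical cohort; `runPipeline()` threads one
  global seed through every stage.

Effect sizes are not reported for the real data, so the defaults above
were chosen once to make planted-signal recovery realistic rather than
trivial: baseline statics classify near chance when only decline rates
differ, dynamic features then reach high-90s accuracy, and the ordering
reverses when only baseline levels differ.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: PET physics (point-spread, attenuation,
partial-volume effects), spatially correlated noise, anatomically
realistic region geometry, registration error, and subject dropout. The
generator validates the *pipeline*, not the clinical effect size.

# Problem sizes and numerical tolerances

The test suite exercises the full study-scale configuration (79 subjects,
246 regions, 4 timepoints) for the signal-recovery checks and a 14-subject,
18-region cohort for unit-level properties; null calibration of the voxel
test uses 50 replicates of 6-vs-6 groups on 10×10×10 grids. Formula-level
oracles (brute-force F-score, scalar-loop dynamic features, concordance
AUC, margin-product chi-square expectations) are held to 1e-10..1e-12;
Monte-Carlo checks use 3-standard-error bands plus the binomial error of
the replicate count. NIfTI volumes are written with double-precision
storage so disk round trips are exact.

# Known limitations

- **Null behaviour of the LOO protocol.** Leave-one-out with within-fold
  feature selection is *pessimistically biased* under label permutation:
  the selected features fit the training set's spurious separation, the
  held-out subject tends to land on the wrong side, and class imbalance
  adds a small label-leakage term. On permuted labels the protocol's mean
  accuracy (computed by `scripts/acceptance.R`, quantity
  `permutation_null_mean_acc`) sits several points *below* the
  majority-class rate rather than at it. This is a property of the
  published protocol itself, faithfully reproduced; chance-level here
  means "no usable signal", not "accuracy equal to the majority rate".
- F-score ranking is univariate and ignores feature interactions and
  redundancy; combining blocks can therefore underperform single blocks.
- The argmax-$k$ reporting mode is optimistic by construction; use the
  nested mode for honest generalisation estimates.
- The generator's simplifications above.
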