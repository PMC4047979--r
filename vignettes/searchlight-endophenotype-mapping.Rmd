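---
title: "Searchlight SVM mapping of candidate endophenotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searchlight SVM mapping of candidate endophenotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A candidate endophenotype is a brain feature that separates affected
individuals from controls *and* separates their unaffected siblings from
controls: if a structural difference is present in both comparisons at the
same location, it is heritable risk rather than expressed condition.
Voxel-based morphometry tests every voxel separately and, in family designs
where effect sizes are diluted, often finds nothing that survives correction.
`endolight` implements the multivariate alternative: a searchlight
(information-mapping) analysis in which a small region is scanned across the
brain and each region is scored by how well a classifier separates two groups
using the region's voxels *jointly*.

# The method

## Searchlight geometry

Input volumes are spatially normalized gray-matter maps on a common grid.
The analysis mask keeps voxels whose gray-matter value exceeds a threshold
(default 0.1) in at least half the participants. Every in-mask voxel is the
centre of one cubic region of edge `side` (default 5, so 125 voxels),
clipped at the grid boundary and restricted to in-mask voxels. Regions
overlap heavily — there are as many regions as centre voxels — giving an
exhaustive scan of the parenchyma. Cubes rather than spheres keep the
geometry and the implementation simple; at this radius the difference is a
few corner voxels.

All voxel coordinates in the package are 1-based `(i, j, k)` array indices,
the R convention; the voxel-to-world affine is carried through I/O but the
algorithm itself works in grid indices, which suffice for maps already in a
common stereotactic space.

## Region classifier

Each region is scored by the cross-validated accuracy of a linear
soft-margin support vector machine with decision rule

    g(x) = w'x + w0,

trained on the region's participants-by-voxels feature matrix with margin
penalty `C = 1` (the customary default; at these sample sizes the solution
is insensitive to it). Accuracy is estimated by stratified 10-fold
cross-validation: within each class, participants are shuffled with a seeded
RNG and dealt round-robin into folds, so every fold has near-equal class
composition; reported accuracy pools correct predictions over all
participants. Stratification matters: with 40-52 participants per group and
10 folds, unstratified folds can produce single-class training sets, and
balanced folds make the null expectation of accuracy exactly 50%.

The solver is a deterministic dual coordinate descent for the L1-loss
(hinge) SVM (the algorithm of Hsieh et al. 2008), written in C++ with two
engineering choices that matter here:

* **Training-mean centring.** Feature columns are centred on their
  training-fold means (the offset is folded back into `w0`). Gray-matter
  features sit around a common tissue baseline (~0.6), which would otherwise
  dominate every inner product and ill-condition the dual; centring also
  makes the fitted rule exactly invariant to a global additive shift of all
  features, a property the test suite asserts.
* **Loose dual tolerance with active-set shrinking.** The stopping tolerance
  defaults to 0.1 with liblinear-style shrinking of firmly-bounded dual
  variables. Held-out accuracy is insensitive to tight dual optimality
  (measured: per-region accuracy correlates 0.99 between tolerances 1e-3
  and 0.1 with mean absolute difference below 0.01, on a statistic whose
  between-region spread is 0.08), while the permutation stage runs an order
  of magnitude faster. The solver visits coordinates in a random order
  re-drawn each epoch from a private fixed-seed generator, so results are
  bit-reproducible and independent of R's RNG state.

On well-separated data the fitted rule agrees with libsvm (`e1071::svm`)
prediction-for-prediction; the suite cross-checks this. Ties at `g(x) = 0`
predict the negative class, a measure-zero convention.

Feature standardization inside regions is off by default (gray-matter maps
are already on a common scale and the cube is small); a `standardize` flag
is exposed for data where voxel scales differ.

## Permutation inference and FDR

Region accuracies have no usable parametric null, so significance is
assessed by label permutation: the full procedure is repeated `B` times
(default 1000) with uniformly permuted group labels, and

    p = #{ b : accuracy_b > observed } / B.

Two details are deliberate:

* **Each permutation re-runs the whole procedure, stratified fold
  assignment included.** Re-using the observed run's fold partition looks
  cheaper but is miscalibrated: folds stratified for the *observed* labels
  are unbalanced for permuted labels, which systematically depresses
  permuted accuracies and inflates significance everywhere (in a null
  experiment roughly half of all regions reached p ≤ 0.05 that way). With
  per-permutation folds the permuted accuracies are exchangeable with the
  observed one under the null, and the package's calibration tests pass.
* **The strictly-greater count is the default estimator.** It can return
  p = 0 and, because cross-validated accuracy is discrete, resolves ties in
  favour of the observed statistic, making it slightly liberal; the
  `plus_one` estimator `(count + 1)/(B + 1)` is offered, and both the
  exceedance and tie counts are returned so a fully conservative value
  `(n_exceed + n_tie + 1)/(B + 1)` can be formed. The test suite brackets
  the estimator between its provable liberal and conservative bounds.

By default one seeded set of B permutations (and their fold partitions) is
shared across regions — exchangeability is a property of the labels, not of
any region — which keeps the permutation stage at `B + 1` model fits per
region; per-region independent draws are available.

Multiple comparisons are handled by Benjamini-Hochberg step-up control at
`alpha = 0.05` over all region p-values (via `stats::p.adjust`); the
rejection set, the step-up rank and the applied p-cutoff are returned.

## Maps, overlap, atlas accounting, transfer

Significant-region accuracies are projected to voxels by **max-projection**:
each voxel receives the highest accuracy among significant regions that
contain it. The candidate-endophenotype map is the voxelwise intersection of
the two comparisons' significance maps (controls vs cases, controls vs
siblings). Against a labelled atlas the package reports, per anatomical
region, the significant-voxel counts and percentages for each comparison and
for the intersection, sorted by common-voxel count; all-zero rows are
dropped. The percentage denominator is the atlas region's size.

Max-projection trades localization for sensitivity: a significant region
marks *all* its member voxels, so a focal effect appears dilated by up to
`side - 1` voxels. Recovered maps should be read as "within one searchlight
radius of informative tissue".

The **transfer experiment** asks whether siblings express the case pattern,
region by region: the positive rate of cases (fraction of cases classified
as case under the same stratified cross-validation) is compared with the
fraction of siblings labelled as case by a single classifier trained on all
controls and cases of that region. The paper-level criterion is a band of
10 percentage points on the absolute difference; matched rates indicate a
shared pattern. Training one final classifier on all controls and cases
(rather than per-fold ensembling) is the literal reading of evaluating
siblings "with that trained classifier".

# The phantom generator

Real cohorts of this design are not publicly available, so every stage is
validated on phantoms with known ground truth. A phantom volume is

    smooth(0.6 * ellipsoid) + noise + planted effects,

where the ellipsoid (semi-axes 0.45 of each grid dimension) stands in for
brain parenchyma at a gray-matter value of 0.6, and the noise is white
Gaussian noise smoothed with a separable Gaussian kernel (`smooth_sigma`
voxels, default 1.5) and rescaled so the interior per-voxel standard
deviation equals `noise_sd` (default 0.1). Rescaling keeps effect sizes,
expressed in units of `noise_sd`, meaningful regardless of smoothing:
a `mean_shift` of magnitude d gives voxelwise two-sample t statistics of
about `d * sqrt(n/2)`.

Two effect modes are provided:

* `mean_shift` adds `magnitude * noise_sd` to every region voxel of affected
  participants — a focal difference visible to univariate tests and to the
  searchlight alike.
* `distributed_pattern` plants a multivariate-only effect: affected
  participants are displaced along a fixed spatial signature (truncated
  Gaussian weights, unit norm) scaled so the joint displacement has length
  `magnitude * noise_sd` while each single-voxel shift is of order
  `2 * magnitude * noise_sd / sqrt(R)` for an R-voxel region. At the default
  region size no voxelwise test survives FDR correction, yet the region
  classifier separates the groups well above chance — the scenario in which
  relations among voxels carry the signal. A generation-time check rejects
  configurations whose largest per-voxel shift exceeds `0.5 * noise_sd`.

A design note on why the multivariate-only mode is a *displacement* rather
than a pure covariance change: for any construction whose class means are
exactly equal, the population hinge objective of a linear SVM is stationary
at `w = 0` and convex, so the trivial classifier is its global optimum — a
linear machine cannot beat chance on mean-balanced classes, whatever the
covariance structure. A multivariate-only effect that a linear searchlight
can legitimately find must therefore live in a *thinly spread* mean
difference, sub-detectable per voxel; that is what `distributed_pattern`
plants.

What the phantoms do **not** emulate: real cortical geometry and
registration error, site/scanner effects, motion and bias-field artifacts,
and the age/sex/IQ covariate structure of real cohorts. Passing the phantom
suite shows the machinery is calibrated and recovers planted signal under
its own assumptions; it does not certify sensitivity on real data.

`generate_atlas()` partitions the phantom brain into contiguous labels by
nearest-seed Voronoi growth, a synthetic stand-in for an anatomical
parcellation used only to exercise the reporting stage.

# Reproducibility and seeds

Everything stochastic flows from explicit integer seeds. Each region's fold
assignment is seeded by a deterministic hash of `(global seed, centre
index)`, so results are identical whatever the processing order or centre
subset — a subset run reproduces the full run's values for shared centres.
Permutation b draws its labels and folds from `(permutation seed, b)`. The
library never mutates the caller's `.Random.seed`.

# Problem sizes used by the validation suite

The automated tests exercise the method at desk scale, chosen to finish in
minutes on one CPU while keeping the study's design parameters (two groups
of 40, side-5 cubes, 10-fold cross-validation, BH at 0.05):

* *Chance calibration*: null phantom, 24³ grid, 40 vs 40, ~960 regions on a
  stride-2 centre lattice, B = 99 permutations. Mean accuracy is compared to
  50% within two Monte-Carlo standard errors estimated from disjoint
  side-5 blocks of centres — overlapping regions are spatially correlated,
  so a naive per-region SE would be too small. One further caveat observed
  in development and worth knowing: all regions share the same participants,
  so a cohort-level accuracy component (a few percentage points between
  phantom draws at n = 80) survives averaging over regions; the region count
  cannot shrink it.
* *Effect recovery*: 44³ grid, radius-15 planted ball shared by cases and
  siblings (magnitude 2.5), 40/40/40, stride-4 centres, B = 33. The common
  map's Dice overlap with the planted truth must exceed 0.5; the effect must
  dominate the atlas report. The effect is deliberately large relative to
  the searchlight radius because max-projection dilation bounds the
  achievable Dice of a small effect from above.
* *Multivariate-only detection*: 20³ grid, 125-voxel `distributed_pattern`
  at pattern magnitude 2.5, 40 vs 40: region accuracy above 65% with zero
  BH-significant voxelwise t tests across the whole mask.
* *Transfer*: 20³ grid, side-7 cube (magnitude 2.5); when siblings share the
  case effect most affected regions fall inside the 10-point band, when
  siblings are drawn like controls they fall outside.

The acceptance script (`scripts/acceptance.R`) regenerates the null phantom
at a caller-supplied seed and reports the searchlight's mean accuracy over
all ~7600 regions, the chance-calibration figure of the method.

# Known limitations

* Pooled (raw) accuracy is the reported statistic, matching the method's
  published description; with unbalanced groups (e.g. 52 vs 40) it is not
  chance-corrected. Stratified folds keep the null at 50%, and a balanced
  reading can be derived from `cv_predict()` if needed.
* No covariate adjustment (age, sex, IQ, total GM volume); inputs are
  assumed already normalized and comparable.
* Max-projection dilation limits localization to one searchlight radius.
* The overlap of two significance maps is reported descriptively, without a
  statistical test on the overlap itself.
* Linear kernel only; the package deliberately omits nonlinear kernels and
  in-region feature selection, which the mapped statistic does not need and
  which would complicate the permutation null.
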