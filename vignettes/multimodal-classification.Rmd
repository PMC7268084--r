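---
title: "Multimodal single-subject classification: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal single-subject classification: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

neurofuse implements a complete multimodal single-subject classification
pipeline for case-control neuroimaging studies: six feature families
(voxel-wise gray and white matter, a per-subject morphological covariance
network, ReHo, ALFF, and a regional functional connectome), control-fitted
Gaussian-process confound removal, per-measure calibrated linear SVMs fused
by soft voting with double-nested stratified cross-validation, permutation
inference, pooled / site-stratified / cross-site evaluation, and
linear-weight region attribution. This vignette records the models, the
tunable parameters, and every place where the design was genuinely open -
and what a green test does and does not establish.

## Feature models

**Voxel-wise structural features.** Gray and white matter maps are smoothed
with a 6 mm full-width-at-half-maximum Gaussian kernel (`fwhm_mm`, mm;
per-axis sigma is `fwhm / (2 sqrt(2 ln 2))` divided by the voxel size) and
flattened over the in-brain mask in column-major raster order. Boundary
handling is renormalized convolution (smoothing the all-ones field and
dividing), so constant maps are exact fixed points. Modulated-volume
semantics (Jacobian scaling during normalization) are assumed already
applied to the inputs; the package starts from preprocessed-equivalent
maps.

**Morphological covariance network.** For every pair of atlas regions we
estimate each region's gray-matter value distribution with a Gaussian
kernel density estimate - Silverman's bandwidth with a degeneracy floor of
`1e-3 x` (value range, or 1 for a constant region) - on a shared grid
spanning the pooled min/max of the two regions padded by three bandwidths
(`kde_grid` points, default 512). The edge weight is
`exp(-[KL(p||q) + KL(q||p)])` with trapezoidal quadrature and a `1e-12`
density floor, giving a similarity in (0, 1] that is exactly 1 for
identical distributions. The cited construction names no estimator,
bandwidth, symmetrization, or divergence-to-similarity map; these choices
are conventions of this package, kept configurable, and the C++ network
builder is cross-checked in the tests against an independent R composition
of pairwise similarities. For classification the matrix is vectorized as
its strict upper triangle in row-major order (R(R-1)/2 features).

**Functional cleaning contract.** In order: discard the first 10 volumes;
censor frames with Power framewise displacement above 0.5 mm (FD uses a
50 mm head radius; rotations are radians - a degree-valued trace cannot be
detected, so the unit is stated loudly in the documentation); linear
detrend; zero-phase order-4 Butterworth bandpass 0.01-0.08 Hz (the published
description names no filter; the design is validated coefficient-for-
coefficient against the reference scipy implementation in the tests);
regression of the global, white-matter-proxy and CSF-proxy mean series
plus the Friston-24 motion expansion, every regressor detrended and
filtered identically to avoid spectral mismatch. Censoring removes exactly
the FD-flagged frames (no 1-back/2-forward augmentation). A subject is
flagged for exclusion when any post-discard translation exceeds 1.5 mm or
any rotation exceeds 1.5 degrees. Published descriptions of this pipeline
are sometimes garbled about which motion regressor set enters the nuisance
model; this package regresses the full Friston-24 expansion, the standard
companion to FD scrubbing. On synthetic data the white-matter and
CSF proxies are designated atlas regions (`wm_region`, `csf_region`,
defaulting to the last two region codes).

**ReHo.** Kendall's coefficient of concordance between a voxel and its up
to 26 in-mask neighbours, computed from average ranks without tie
correction (ties have measure zero for continuous data); border voxels use
their available neighbours with K adjusted. **ALFF.** The mean amplitude
spectrum (square root of the power spectrum) over the 0.01-0.08 Hz bins of
the cleaned series; `alff_on_unfiltered` switches to the common
alternative convention of computing it before the bandpass. Both maps are
divided by their in-mask mean (post-division mean exactly 1), so only
spatial patterns - not global scale - enter the classifiers.
**Functional connectome.** Pearson correlations of regional mean series
over the kept frames.

## Confound removal

A Gaussian-process regression of each feature on standardized (age, sex)
is fitted **on control subjects only** - the patient-control difference
itself can then never enter the confound model - with kernel
`linear + squared-exponential + white noise`. The (age, sex)-varying part
of the prediction is subtracted, preserving feature means, so a flat model
is the identity. Two departures from a naive reading are deliberate:

* **Hyperparameters are shared across the features of a measure**,
  optimized on the mean log marginal likelihood of at most 32 seeded,
  standardized feature columns (Nelder-Mead in log-space, seeded
  restarts). Each feature keeps its own posterior mean (its own weights);
  only the kernel is shared. Full per-feature marginal-likelihood
  optimization over ~1300 voxel features in every training fold is
  computationally indefensible, and with standardized inputs a shared
  kernel is the natural multi-feature model.
* **Leakage policy.** By default the confound model is refitted inside
  every outer training fold (`confound = "fold"`), keeping test folds
  untouched; `confound = "whole_sample"` reproduces the one-shot fit
  a surface reading of the published description suggests. Whether connectivity matrices
  are residualized edge-wise or after vectorization is unstated;
  we residualize the vectorized features, which is equivalent
  edge-wise because the model is independent per feature.

## Classification engine

Per measure, a linear soft-margin SVM (dual coordinate descent, the
LIBLINEAR algorithm, stopping tolerance 0.1, bias via an appended
constant column; features standardized by training-fold statistics) with
`C` selected from `10^-3 ... 10^4` by inner stratified cross-validation on
mean balanced accuracy, ties toward the smaller `C`. Class probabilities
come from Platt scaling - a monotone sigmoid of the decision value fitted
on the training-fold decisions by Newton iteration with Platt's smoothed
targets. The reference implementation's "library default" internal-CV
calibration is approximated by this direct fit (configurable folds would
multiply the fit count by their number); single-measure *labels* use the
sign of the decision value, as the reference library does, so calibration
affects only the fusion stage.

Fusion is soft voting: fused patient score
`sum_m c_m p_m / sum_m c_m` with integer coefficients `c_m` in 1..10
chosen by a second nested search on **cached** inner out-of-fold
probabilities (no refitting): `full_grid` enumerates all 10^M
combinations in lexicographic order (refused above M = 6), `greedy`
(default) is two sweeps of coordinate ascent from all-ones. Ties resolve
to the lexicographically smallest vector; exact fused-score ties predict
the patient class. The cache is proven equivalent to refit-based selection
in the acceptance tests. One combined run also reports every
single-measure result, because each measure's refitted model is evaluated
on the same outer test folds.

Permutation inference re-runs the whole training process on label-permuted
data with outer folds re-seeded per replicate, and reports
`p = #(permuted BAC > observed BAC) / n_permutations` - the strict
inequality, no add-one; `conservative = TRUE` gives `(b+1)/(n+1)`.
Cross-site evaluation tunes everything (confounds, C, coefficients) by
nested CV within the training site and evaluates once on the test site.
Class imbalance is handled only through stratification and balanced
accuracy - no resampling or class weights.

A phenomenon worth knowing when reading null results: nested CV on null
data is *finite-sample pessimistic*. Selecting `C` by inner balanced
accuracy, especially with a strong group-orthogonal nuisance axis (site),
centers the outer balanced accuracy a few points **below** 50% at small n
(we measure ~41-45% at n = 48, recovering to ~48-50% at n = 96). This is
a property of nested selection, not leakage; the calibration tests
therefore use the fused pipeline at sizes where the bias has decayed, and
the below-chance direction is the conservative one.

## Synthetic cohorts: the stated world

The generator draws a two-group, optionally multi-site cohort on a seeded
Voronoi atlas (ellipsoidal mask, contiguous regions, >= 8 voxels each;
default test geometry 16x16x16, R = 12, T = 120, TR = 2 s, 3 mm voxels).

* **Structural maps**: subject baseline (SD 0.05) + a fixed smooth spatial
  profile + voxel noise (SD 0.08) + age/sex/site terms. Patients receive
  an additive shift in affected regions calibrated so `struct_effect_d`
  is literally Cohen's d on the across-subject distribution of region
  means (white matter at 0.7 of it).
* **BOLD**: per-region latent signals - 0.01-0.08 Hz band-limited noise
  plus a 10% AR(1) broadband component - correlated across regions by a
  latent correlation matrix (base 0.2), mixed into member voxels with
  shared-signal fraction kappa (base 0.45). Voxel noise is itself mostly
  band-limited: with white voxel noise the cleaning bandpass would
  inflate every voxel's effective coherence toward 1 and crush the ReHo
  contrast, a subtlety worth a sentence because it dictated the model.
  Patients: kappa + `coherence_shift` in affected regions (ReHo handle),
  whole-series gain `amplitude_shift` (ALFF handle - rank- and
  correlation-invariant by construction, so it moves neither ReHo nor
  connectivity), and `fc_shift` added to affected edges with alternating
  sign (a uniformly positive shift would be largely removed by
  global-signal regression, exactly as in real data).
* **Disease defaults** (`disease_effects()`): d = 1.5,
  coherence +0.3, amplitude x1.5, connectivity +/-0.45, on regions 1-4.
  Magnitudes were fixed once, on effect-size grounds: after the cleaning
  contract (GSR included) they correspond to clearly expressed per-feature
  effects (t of roughly 3-7 at n = 40-120), i.e. a detectable illness, not
  a borderline one. The published study reports no effect-size ground truth, so
  these are free parameters of the stated world, documented here and not
  revisited.
* **Confounds and sites**: age (years) and sex slopes on structural maps;
  log-gain age/sex terms on even-numbered regions' BOLD amplitude (a
  global gain would cancel in the normalized maps). Site nuisances are
  regionally patterned - additive structural offset on odd regions, global
  structural gain, coherence offset on odd regions, amplitude gain on odd
  regions, checkerboard-signed connectivity offset - because spatially
  uniform offsets are invisible to a linear contrast and would not
  reproduce the cross-site transfer collapse that multi-site studies
  actually show. `make_site_offsets(..., "large")` is the documented
  "site effects dominate group effects" regime.
* **Motion**: per-frame random walks (0.01 mm, 2e-4 rad) with optional
  translation spikes (default probability 0.01, 0.8 mm) that trip the FD
  scrubber but not the exclusion limits.

What the generator does **not** emulate: anatomy, hemodynamics, spatial
autocorrelation of noise, scanner drift, physiological rhythms,
distance-dependent connectivity, or realistic confound-effect sizes. A
green recovery test therefore establishes that the pipeline's inference
machinery is correct and calibrated on data whose generating process
matches its assumptions - not that comparable accuracies are attainable on
any real cohort.

## Numerical choices

* NIfTI-1 I/O is a minimal built-in reader/writer (float64/int32, sform
  affine, little-endian; reading tolerates both endiannesses and common
  datatypes) because no NIfTI package exists in the supported environment;
  round trips are bit-exact and cross-checked against nibabel.
* Butterworth design uses the analog prototype -> bandpass transform ->
  bilinear mapping with pre-warping; `filtfilt` uses odd-symmetric edge
  padding of length `3 x (filter length - 1)` with steady-state initial
  conditions.
* Kendall's W is computed without tie correction; average ranks for ties.
* Rounding of reported percentages is half-away-from-zero at 2 decimals
  (the reference tables' convention is unstated; this one is fixed so the
  aggregation arithmetic is reproducible).
* Determinism: every source of randomness derives from one integer seed
  through a splitmix-style child-seed chain; identical (data, config,
  seed) give identical results, byte-for-byte after serialization.
* Runtime scalings in the test suite (documented, not hidden): the heavy
  acceptance arms run with 5 inner folds (C grid unchanged) and the
  signal/site arms with 5 outer folds; fold counts change the variance,
  not the expectation, of the measured quantities.

## Region attribution

Fused soft voting has no joint weight vector, so attribution is
per measure, mirroring how such tables are reported: for connectome
measures the absolute weights are folded back into a symmetric matrix and
each region gets the mean of its R-1 edge weights; for voxel measures the
mean absolute weight over the region's voxels. `|w|` is taken per fold and
then averaged (the alternative order is ambiguous as published; this one
is documented). Multivariate weights are not localizers: a region can rank
high through its correlations with others, so the top-k lists should be
read as a distributed pattern - the attribution sanity test is accordingly
weak (recovering at least half of the truly affected set).

## Known limitations

* No site harmonization (explicitly out of scope; the cross-site and
  pooled results are the motivation for such methods, not a substitute).
* The GP confound model shares kernel hyperparameters within a measure;
  features whose confound length-scales differ wildly are averaged over.
* Platt calibration is fitted on in-sample decision values; with few
  subjects the fused probabilities are optimistic near the margins,
  which the coefficient search partially absorbs.
* The permutation test re-runs the full nested pipeline and is priced
  accordingly; the default 1000 permutations is a batch-compute setting,
  and tests use 99.
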