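# neurofuse

Single-subject classification of patients versus controls from multimodal
brain imaging, for methodologists who want the full pipeline — features,
confound control, nested model selection, fusion, inference — as tested,
reusable code rather than a paper's prose description.

Psychiatric disorders such as schizophrenia show both structural and
functional brain alterations, and classifiers built on a single imaging
measure plateau well below what a combination can reach. neurofuse
implements a complete multimodal framework:

* **Six feature families** per subject: voxel-wise gray matter (GM) and
  white matter (WM) maps; a *morphological covariance network* — region ×
  region similarity `exp(−[KL(p‖q) + KL(q‖p)])` between kernel density
  estimates of two regions' gray-matter values; *ReHo* — Kendall's
  coefficient of concordance `W = 12 Σ_t (R_t − K(n+1)/2)² / (K²(n³−n))`
  over each voxel's 27-voxel neighbourhood; *ALFF* — the mean amplitude
  spectrum in 0.01–0.08 Hz; and the regional Pearson functional
  connectome.
* **Cleaning contract** for resting-state series: volume discard, Power
  framewise-displacement scrubbing (FD > 0.5 mm), linear detrend,
  zero-phase order-4 Butterworth bandpass, global/WM/CSF + Friston-24
  nuisance regression, and 1.5 mm / 1.5° gross-motion exclusion.
* **Confound control**: Gaussian-process regression of every feature on
  (age, sex), fitted on controls only, subtracted before classification.
* **Classifier**: per-measure calibrated linear SVMs with the soft-margin
  parameter chosen on an inner stratified 10-fold loop
  (C ∈ 10⁻³…10⁴), fused by *soft voting* — fused patient score
  `Σ_m c_m p_m / Σ_m c_m` with integer coefficients `c_m ∈ 1..10` chosen
  by a second nested search on cached out-of-fold probabilities — and
  evaluated by outer stratified 10-fold CV in balanced accuracy (BAC),
  sensitivity and specificity, with label-permutation p-values.
* **Multi-site tooling**: pooled and site-stratified evaluation,
  train-on-one-site / test-on-another transfer, and per-region attribution
  from the linear weights.
* **A synthetic multimodal cohort generator** with known ground truth
  (structural effect sizes, coherence / amplitude / connectivity shifts,
  age–sex confounds, per-site nuisances), so the whole pipeline is
  testable end-to-end without downloading any data, plus a minimal
  NIfTI-1 reader/writer and BIDS-flavoured cohort I/O.

## Worked example

```r
library(neurofuse)

atlas  <- generate_atlas(c(16, 16, 16), R = 12, seed = 3)
cohort <- generate_cohort(20, atlas, disease_effects(),   # 20 per group
                          T = 120, tr = 2, seed = 5)
feats  <- compute_measures(cohort)                        # all six measures
cfg    <- classifier_config(outer_folds = 10, inner_folds = 5, seed = 9)
res    <- run_cv(feats$measures, feats$meta, cfg, mode = "combined")
print(res)
#> <ensemble_result> combined over GM+WM+StructM+ReHo+ALFF+FuncM: BAC 100.00%, SEN 100.00%, SPEC 100.00%
for (m in names(res$per_measure))
  cat(sprintf("%-8s BAC %6.2f%%\n", m, res$per_measure[[m]]$mean_bac))
#> GM       BAC 100.00%
#> WM       BAC 100.00%
#> StructM  BAC 100.00%
#> ReHo     BAC  90.00%
#> ALFF     BAC  87.50%
#> FuncM    BAC  90.00%
```

The cohort carries the package's documented disease model
(`disease_effects()`: structural d = 1.5 in regions 1–4, coherence +0.3,
amplitude ×1.5, connectivity ±0.45). With 20 subjects per group the
structural measures separate the groups completely and each functional
measure classifies 87–90% of held-out subjects correctly; the fused model
reaches 100% — the combined-beats-single ordering the method is designed
to exhibit. A null cohort (`effect_spec()`, all effects zero) centers at
50% BAC, and `permutation_test()` prices significance by re-running the
entire nested pipeline on shuffled labels.

Region attribution from the fold-1 GM weights:

```r
rw <- region_weights_voxel_measure(res$weights[[1]]$GM, atlas)
head(top_regions(cbind(run1 = rw), k = 5), 3)
#>       region       run1       mean
#> 1 region_008 0.07021828 0.07021828
#> 2 region_009 0.06734692 0.06734692
#> 3 region_007 0.06502178 0.06502178
```

(Linear-SVM weights are a distributed pattern, not a localizer — see the
methods vignette.)

## Command line

A small front end for cohort directories written by `write_cohort()`:

```sh
Rscript inst/cli/neurofuse.R classify   --cohort myco --measures gm,reho --seed 1
Rscript inst/cli/neurofuse.R permute    --cohort myco --n-perm 99
Rscript inst/cli/neurofuse.R cross-site --train siteA --test siteB
```

## Further reading

`vignettes/multimodal-classification.Rmd` documents the models and their
assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, the numerical choices
(filters, bandwidth floors, tie-breaks, rounding), and known limitations —
including why nested cross-validation on null data sits slightly below
chance in finite samples.
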