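Package: neurofuse
Title: Multimodal Neuroimaging Classification with Soft-Voting SVM Ensembles
Version: 0.1.0
Authors@R:
    person("Neurofuse", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for single-subject classification from multimodal
    brain-imaging measures. Implements voxel-wise gray and white matter
    features, Kullback-Leibler divergence based morphological covariance
    networks, regional homogeneity (ReHo), amplitude of low-frequency
    fluctuation (ALFF), and region-level Pearson functional connectomes;
    Gaussian-process regression of age and sex confounds fitted on
    controls; per-measure calibrated linear support vector machines fused
    by soft voting with double-nested stratified cross-validation;
    permutation inference, pooled/site-stratified and cross-site
    evaluation; and linear-weight region attribution. Ships a multi-site
    synthetic multimodal cohort generator with known ground truth so the
    full pipeline is testable without any data download, plus a minimal
    NIfTI-1 reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
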