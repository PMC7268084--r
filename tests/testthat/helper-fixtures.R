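# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are cached for the session.

.fix <- new.env(parent = emptyenv())

fix_atlas <- function() {
  if (is.null(.fix$atlas))
    .fix$atlas <- generate_atlas(c(16, 16, 16), R = 12, seed = 3)
  .fix$atlas
}

fix_small_atlas <- function() {
  if (is.null(.fix$small_atlas))
    .fix$small_atlas <- generate_atlas(c(10, 10, 10), R = 4, seed = 2)
  .fix$small_atlas
}

# A T x V matrix laid into a bold_series on a fully-true mask, so column v
# of the matrix is in-mask voxel v in the package's ordering.
matrix_as_bold <- function(X, dims, tr = 2) {
  stopifnot(prod(dims) == ncol(X))
  flat <- t(X)
  bold_series(array(flat, c(dims, nrow(X))), tr, array(TRUE, dims))
}

# Brute-force Kendall's W of a T x K block (average ranks, no tie
# correction) - independent of the package's C++ path.
kendall_w_bruteforce <- function(block) {
  n <- nrow(block)
  K <- ncol(block)
  R <- apply(block, 2, rank)
  rs <- rowSums(R)
  12 * sum((rs - K * (n + 1) / 2)^2) / (K^2 * (n^3 - n))
}

# Closed-form Gaussian-mixture KDE value at point g.
kde_value_oracle <- function(g, values, bw) {
  mean(dnorm(g, mean = values, sd = bw))
}

# Silverman bandwidth as specified (duplicated on purpose: oracle).
silverman_oracle <- function(x) {
  spread <- min(sd(x), (quantile(x, .75, names = FALSE) -
                          quantile(x, .25, names = FALSE)) / 1.34)
  rng <- diff(range(x))
  max(0.9 * spread * length(x)^(-1 / 5), 1e-3 * if (rng > 0) rng else 1)
}

# Per-fold balanced accuracy of a soft vote, written independently.
softvote_bac_oracle <- function(P, co, y, fold) {
  score <- as.vector(P %*% co) / sum(co)
  pred <- ifelse(score >= 0.5, "patient", "control")
  mean(sapply(sort(unique(fold)), function(f) {
    i <- fold == f
    sen <- mean(pred[i][y[i] == "patient"] == "patient")
    spec <- mean(pred[i][y[i] == "control"] == "control")
    50 * (sen + spec)
  }))
}

# Quick generator for aligned random measure_features tables.
random_measures <- function(n, dims, ids, seed) {
  set.seed(seed)
  out <- list()
  for (m in names(dims))
    out[[m]] <- measure_features(matrix(rnorm(n * dims[[m]]), n), m, ids)
  out
}

null_meta <- function(n, seed) {
  set.seed(seed)
  data.frame(participant_id = sprintf("s%03d", seq_len(n)),
             group = rep(c("patient", "control"), length.out = n),
             age = rnorm(n, 32, 9),
             sex = sample(c("M", "F"), n, TRUE),
             site = "site1", stringsAsFactors = FALSE)
}
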