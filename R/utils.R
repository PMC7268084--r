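#' @useDynLib neurofuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor dnorm fft lm.fit optim predict quantile rbinom
#'   rnorm runif sd var
#' @importFrom utils read.delim write.table head
NULL

# Round half away from zero at `digits` decimals (base round() is banker's).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

trapz_int <- function(grid, y) {
  n <- length(grid)
  sum(0.5 * diff(grid) * (y[-1] + y[-n]))
}

# Deterministic child seed kept inside 32-bit integer range.
child_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in ks) s <- (s * 69069 + as.double(k) * 7901 + 1) %% 2147483629
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stratified fold assignment: within each stratum, shuffled indices are dealt
# round-robin, so fold sizes differ by at most one per stratum. Deterministic.
stratified_folds <- function(strata, k, seed) {
  strata <- as.factor(strata)
  fold <- integer(length(strata))
  with_seed(seed, {
    for (lev in levels(strata)) {
      idx <- which(strata == lev)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
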