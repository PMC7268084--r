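#' Calibrated linear support vector machine
#'
#' Linear soft-margin C-SVM (hinge loss) solved by dual coordinate descent
#' (the LIBLINEAR algorithm; bias handled by an appended constant column),
#' with class probabilities from Platt scaling: a monotone sigmoid
#' `p(patient | f) = 1 / (1 + exp(A f + B))` fitted on the training-fold
#' decision values `f` by Newton iteration with Platt's smoothed targets.
#' Features are standardized by training-fold mean/SD (constant columns
#' tolerated). Deterministic given `seed`.
#'
#' @param X numeric subjects x features matrix.
#' @param y labels, `"patient"` / `"control"` (patient is the positive
#'   class).
#' @param C soft-margin penalty.
#' @param seed integer seed (coordinate order shuffling).
#' @param standardize standardize columns on the training data (default
#'   `TRUE`).
#' @param max_epoch coordinate-descent epoch cap (default 100).
#' @return Object of class `linear_svm` with elements `w` (weights in
#'   original feature units), `b` (intercept), `platt`, `C`.
#' @export
train_calibrated_svm <- function(X, y, C, seed = 1, standardize = TRUE,
                                 max_epoch = 100) {
  X <- as.matrix(X)
  y01 <- as.integer(y == "patient")
  if (length(unique(y01)) < 2)
    stop("train_calibrated_svm: both classes must be present")
  if (standardize) {
    st <- std_stats(X)
    ctr <- st$ctr; scl <- st$scl
    Xs <- scale_cols(X, ctr, scl)
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
    Xs <- X
  }
  # tol 0.1 is the LIBLINEAR default stopping tolerance for the dual
  fit <- cpp_svm_dcd(cbind(Xs, 1), ifelse(y01 == 1, 1, -1), C,
                     tol = 0.1, max_epoch = max_epoch, seed = seed)
  w_s <- fit$w[-length(fit$w)]
  b_s <- fit$w[length(fit$w)]
  w <- w_s / scl
  b <- b_s - sum(w * ctr)
  f <- as.vector(X %*% w + b)
  platt <- platt_fit(f, y01)
  structure(list(w = w, b = b, platt = platt, C = C,
                 epochs = fit$epochs),
            class = "linear_svm")
}

# Lean fitting path for hyperparameter search: no Platt fit, no
# data.frame assembly; returns the decision function only.
svm_decision_fit <- function(Xs, y, C, seed, max_epoch = 100) {
  fit <- cpp_svm_dcd(cbind(Xs, 1), ifelse(y == "patient", 1, -1), C,
                     tol = 0.1, max_epoch = max_epoch, seed = seed)
  fit$w
}

svm_decision_labels <- function(w, Xs) {
  f <- as.vector(Xs %*% w[-length(w)] + w[length(w)])
  ifelse(f >= 0, "patient", "control")
}

# Vectorized column means/SDs (constant columns get scale 1).
std_stats <- function(X) {
  n <- nrow(X)
  ctr <- colMeans(X)
  v <- (colSums(X^2) - n * ctr^2) / (n - 1)
  scl <- sqrt(pmax(v, 0))
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(ctr = ctr, scl = scl)
}

scale_cols <- function(X, ctr, scl) {
  X <- X - rep(ctr, each = nrow(X))
  X / rep(scl, each = nrow(X))
}

# Platt scaling: Newton iteration on the regularized log-loss.
platt_fit <- function(f, y01) {
  np <- sum(y01 == 1); nn <- sum(y01 == 0)
  t <- ifelse(y01 == 1, (np + 1) / (np + 2), 1 / (nn + 2))
  A <- 0
  B <- log((nn + 1) / (np + 1))
  for (it in 1:100) {
    q <- A * f + B
    p <- 1 / (1 + exp(q))
    g <- c(sum((t - p) * f), sum(t - p))
    wgt <- pmax(p * (1 - p), 1e-12)
    H <- matrix(c(sum(wgt * f^2), sum(wgt * f),
                  sum(wgt * f), sum(wgt)), 2) + diag(1e-10, 2)
    step <- solve(H, -g)
    A <- A + step[1]
    B <- B + step[2]
    if (max(abs(step)) < 1e-10) break
  }
  c(A = A, B = B)
}

#' Predict from a calibrated linear SVM
#'
#' @param object a `linear_svm`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return data.frame with `decision`, `prob_patient`, `prob_control`,
#'   `label` (sign of the decision value; exact zero counts as patient).
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  f <- as.vector(as.matrix(newdata) %*% object$w + object$b)
  p <- 1 / (1 + exp(object$platt["A"] * f + object$platt["B"]))
  data.frame(decision = f, prob_patient = p, prob_control = 1 - p,
             label = ifelse(f >= 0, "patient", "control"),
             stringsAsFactors = FALSE)
}
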