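#' Gaussian-process confound model fitted on controls
#'
#' Learns, per feature, how a measure varies with age and sex, using
#' Gaussian-process regression with a linear + squared-exponential + white
#' noise kernel on standardized `(age, sex)` inputs, fitted on control
#' subjects only (so the patient-control difference itself cannot leak into
#' the confound model). Kernel hyperparameters are shared across the
#' features of the measure and chosen by maximizing the mean log marginal
#' likelihood of up to `max_features` seeded, standardized feature columns
#' (with `restarts` seeded restarts); each feature then gets its own
#' posterior mean function. Deterministic given `seed`.
#'
#' @param X a [measure_features()].
#' @param meta data.frame aligned with `X` rows, with columns `group`
#'   (`"patient"`/`"control"`), `age`, `sex` (`"M"`/`"F"`).
#' @param control_only train on controls only (default `TRUE`, the
#'   defensible choice).
#' @param seed integer seed for subsampling/restarts.
#' @param max_features number of feature columns entering the shared
#'   hyperparameter objective (default 32).
#' @param restarts optimizer restarts (default 2).
#' @param maxit Nelder-Mead iteration cap per restart (default 300).
#' @return Object of class `confound_model`.
#' @export
fit_confound_model <- function(X, meta, control_only = TRUE, seed = 1,
                               max_features = 32, restarts = 2,
                               maxit = 300) {
  stopifnot(inherits(X, "measure_features"))
  if (nrow(X$matrix) != nrow(meta))
    stop("fit_confound_model: meta rows do not match feature rows")
  rows <- if (control_only) which(meta$group == "control")
          else seq_len(nrow(meta))
  if (length(rows) < 10)
    stop("fit_confound_model: need >= 10 training rows, got ",
         length(rows))
  age <- meta$age[rows]
  if (var(age) == 0) stop("fit_confound_model: age variance is zero")
  sex <- as.numeric(meta$sex[rows] == "M")
  use_sex <- var(sex) > 0
  if (!use_sex)
    warning("fit_confound_model: all training controls share one sex; ",
            "sex term dropped")
  age_mu <- mean(age)
  age_sd <- sd(age)
  Z <- cbind(age = (age - age_mu) / age_sd, if (use_sex) cbind(sex = sex))
  Y <- X$matrix[rows, , drop = FALSE]
  centers <- colMeans(Y)
  Yc <- sweep(Y, 2, centers)
  sds <- apply(Yc, 2, sd)
  sds[sds == 0] <- 1
  nf <- ncol(Yc)
  sub <- if (nf > max_features)
    with_seed(child_seed(seed, 11L), sort(sample.int(nf, max_features)))
  else seq_len(nf)
  Ys <- sweep(Yc[, sub, drop = FALSE], 2, sds[sub], "/")

  n <- nrow(Z)
  D2 <- as.matrix(stats::dist(Z))^2
  LIN <- tcrossprod(Z)
  nll <- function(th) {
    vl <- exp(th[1]); vf <- exp(th[2]); ll <- exp(th[3]); vn <- exp(th[4])
    if (!all(is.finite(c(vl, vf, ll, vn)))) return(1e10)
    K <- vl * LIN + vf * exp(-D2 / (2 * ll^2)) + diag(vn + 1e-8, n)
    Lc <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(Lc)) return(1e10)
    A <- backsolve(Lc, forwardsolve(t(Lc), Ys))
    mean(0.5 * colSums(Ys * A)) + sum(log(diag(Lc))) +
      0.5 * n * log(2 * pi)
  }
  starts <- list(log(c(1, 1, 1, 0.1)))
  extra <- with_seed(child_seed(seed, 12L),
                     lapply(seq_len(max(restarts - 1, 0)),
                            function(i) log(c(1, 1, 1, 0.1)) +
                              rnorm(4, 0, 1)))
  starts <- c(starts, extra)
  best <- NULL
  for (st in starts) {
    op <- optim(st, nll, method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = 1e-8))
    if (is.null(best) || op$value < best$value) best <- op
  }
  th <- best$par
  vl <- exp(th[1]); vf <- exp(th[2]); ll <- exp(th[3]); vn <- exp(th[4])
  K <- vl * LIN + vf * exp(-D2 / (2 * ll^2)) + diag(vn + 1e-8, n)
  alpha <- solve(K, Yc)
  structure(list(Z = Z, alpha = alpha, centers = centers,
                 theta = c(v_lin = vl, v_se = vf, len = ll, v_noise = vn),
                 age_mu = age_mu, age_sd = age_sd, use_sex = use_sex,
                 measure = X$measure, feature_labels = X$feature_labels,
                 training_ids = X$subject_ids[rows]),
            class = "confound_model")
}

#' @export
print.confound_model <- function(x, ...) {
  cat(sprintf(paste0("<confound_model> %s: %d features, %d controls, ",
                     "kernel (v_lin=%.3g, v_se=%.3g, len=%.3g, ",
                     "v_noise=%.3g)\n"),
              x$measure, length(x$feature_labels), nrow(x$Z),
              x$theta[1], x$theta[2], x$theta[3], x$theta[4]))
  invisible(x)
}

confound_predict <- function(model, meta) {
  age <- (meta$age - model$age_mu) / model$age_sd
  Znew <- cbind(age = age,
                if (model$use_sex) cbind(sex = as.numeric(meta$sex == "M")))
  vl <- model$theta[1]; vf <- model$theta[2]; ll <- model$theta[3]
  D2 <- outer(rowSums(Znew^2), rowSums(model$Z^2), "+") -
    2 * tcrossprod(Znew, model$Z)
  D2[D2 < 0] <- 0
  Ks <- vl * tcrossprod(Znew, model$Z) + vf * exp(-D2 / (2 * ll^2))
  sweep(Ks %*% model$alpha, 2, model$centers, "+")
}

#' Remove age/sex-related variance from a feature table
#'
#' Subtracts the (age, sex)-varying part of the confound model's
#' prediction - prediction minus the per-feature training mean - from each
#' subject's features. Feature means are preserved, a flat model is the
#' identity, and shape/alignment are untouched; the residuals are what the
#' classifiers consume.
#'
#' @param X a [measure_features()].
#' @param model a [fit_confound_model()] result for the same feature space.
#' @param meta metadata aligned with `X`.
#' @return A residualized [measure_features()].
#' @export
residualize <- function(X, model, meta) {
  if (!inherits(model, "confound_model"))
    stop("residualize: need a confound_model")
  if (!identical(model$feature_labels, X$feature_labels))
    stop("residualize: feature labels do not match the model")
  preds <- confound_predict(model, meta)
  varying <- sweep(preds, 2, model$centers)
  measure_features(X$matrix - varying, X$measure, X$subject_ids,
                   X$feature_labels)
}
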