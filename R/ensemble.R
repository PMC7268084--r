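#' Classifier and cross-validation configuration
#'
#' @param C_grid soft-margin grid searched in the inner loop (default
#'   `10^(-3:4)`).
#' @param outer_folds,inner_folds stratified fold counts (default 10/10).
#' @param coeff_range integer soft-voting coefficient grid (default 1..10).
#' @param n_permutations label permutations for [permutation_test()]
#'   (default 1000).
#' @param seed master seed; every internal source of randomness derives
#'   from it.
#' @param coeff_search `"greedy"` (coordinate ascent from all-ones, 2
#'   sweeps) or `"full_grid"` (exhaustive over the cached probabilities;
#'   refused for more than 6 measures).
#' @param confound `"fold"` (fit the confound model on each training
#'   fold's controls; default, leakage-safe), `"whole_sample"` (one-shot fit on
#'   all controls before cross-validation), or `"none"`.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(C_grid = 10^(-3:4), outer_folds = 10,
                              inner_folds = 10, coeff_range = 1:10,
                              n_permutations = 1000, seed = 1,
                              coeff_search = c("greedy", "full_grid"),
                              confound = c("fold", "whole_sample", "none")) {
  if (outer_folds < 2 || inner_folds < 2)
    stop("classifier_config: folds must be >= 2")
  structure(list(C_grid = sort(C_grid), outer_folds = outer_folds,
                 inner_folds = inner_folds,
                 coeff_range = as.integer(coeff_range),
                 n_permutations = n_permutations, seed = seed,
                 coeff_search = match.arg(coeff_search),
                 confound = match.arg(confound)),
            class = "classifier_config")
}

# Inner-CV selection of the soft-margin parameter: mean inner-fold balanced
# accuracy over a stratified split, ties broken toward the smaller C.
#' Select the SVM soft-margin parameter by nested cross-validation
#'
#' @param X training feature matrix.
#' @param y training labels (`"patient"`/`"control"`).
#' @param cfg a [classifier_config()].
#' @param seed fold/SVM seed (defaults to `cfg$seed`).
#' @param folds optional pre-built inner-fold assignment (shared across
#'   measures by [run_cv()] so cached probabilities are fold-coherent).
#' @return List: `C` (the winner, a member of `cfg$C_grid`), `folds`
#'   (inner fold ids, reusable for probability caching), `bac_by_C`.
#' @export
select_C <- function(X, y, cfg = classifier_config(), seed = cfg$seed,
                     folds = NULL) {
  k <- min(cfg$inner_folds, min(table(y)))
  if (k < cfg$inner_folds)
    warning("select_C: inner folds reduced to ", k,
            " (smallest class size)")
  if (k < 2) stop("select_C: a class has fewer than 2 members")
  if (is.null(folds)) folds <- stratified_folds(y, k, child_seed(seed, 21L))
  k <- max(folds)
  # standardize once per fold; refitting over the C grid reuses the split
  splits <- lapply(seq_len(k), function(f) {
    tr <- folds != f
    st <- std_stats(X[tr, , drop = FALSE])
    list(Xtr = scale_cols(X[tr, , drop = FALSE], st$ctr, st$scl),
         Xte = scale_cols(X[!tr, , drop = FALSE], st$ctr, st$scl),
         ytr = y[tr], yte = y[!tr])
  })
  bac_by_C <- vapply(cfg$C_grid, function(C) {
    mean(vapply(seq_len(k), function(f) {
      sp <- splits[[f]]
      w <- svm_decision_fit(sp$Xtr, sp$ytr, C,
                            seed = child_seed(seed, 22L, f))
      balanced_metrics(sp$yte, svm_decision_labels(w, sp$Xte))["bac"]
    }, numeric(1)))
  }, numeric(1))
  best <- which(bac_by_C > max(bac_by_C) - 1e-12)[1] # first = smallest C
  list(C = cfg$C_grid[best], folds = folds, bac_by_C = bac_by_C)
}

# Out-of-fold calibrated patient probabilities at a fixed C, reusing the
# select_C fold assignment.
oof_probabilities <- function(X, y, C, folds, seed) {
  p <- numeric(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    st <- std_stats(X[tr, , drop = FALSE])
    fit <- train_calibrated_svm(scale_cols(X[tr, , drop = FALSE], st$ctr,
                                           st$scl),
                                y[tr], C, standardize = FALSE,
                                seed = child_seed(seed, 23L, f))
    p[!tr] <- predict(fit, scale_cols(X[!tr, , drop = FALSE], st$ctr,
                                      st$scl))$prob_patient
  }
  p
}

mean_fold_bac <- function(score, y, fold_id) {
  pred <- ifelse(score >= 0.5, "patient", "control")
  mean(vapply(sort(unique(fold_id)), function(f)
    balanced_metrics(y[fold_id == f], pred[fold_id == f])["bac"],
    numeric(1)))
}

#' Select integer soft-voting coefficients on cached probabilities
#'
#' Maximizes the mean inner-fold balanced accuracy of the soft vote over
#' integer coefficients in `cfg$coeff_range`, using per-measure
#' out-of-fold probabilities computed once (no SVM refitting during the
#' search). `"full_grid"` enumerates all combinations (refused above 6
#' measures); `"greedy"` is coordinate ascent from all-ones, two sweeps.
#' Ties resolve to the lexicographically smallest vector.
#'
#' @param probs subjects x measures matrix of cached out-of-fold patient
#'   probabilities.
#' @param fold_id inner-fold assignment used to compute `probs`.
#' @param y training labels.
#' @param cfg a [classifier_config()].
#' @return Integer coefficient vector, one per measure.
#' @export
select_coefficients <- function(probs, fold_id, y, cfg =
                                  classifier_config()) {
  P <- as.matrix(probs)
  M <- ncol(P)
  cmax <- max(cfg$coeff_range)
  if (cfg$coeff_search == "full_grid") {
    if (M > 6)
      stop("select_coefficients: full_grid refused for M = ", M,
           " measures (> 6); use coeff_search = \"greedy\"")
    return(as.integer(cpp_coeff_grid(P, as.integer(y == "patient"),
                                     as.integer(fold_id) - 1L, cmax)))
  }
  co <- rep(1L, M)
  best <- mean_fold_bac(as.vector(P %*% co) / sum(co), y, fold_id)
  for (sweep_i in 1:2) {
    for (m in seq_len(M)) {
      for (cand in cfg$coeff_range) {
        trial <- co
        trial[m] <- cand
        b <- mean_fold_bac(as.vector(P %*% trial) / sum(trial), y, fold_id)
        if (b > best + 1e-12) {
          best <- b
          co <- trial
        }
      }
    }
  }
  co
}

check_alignment <- function(measures, meta) {
  if (is.null(names(measures)) || any(names(measures) == ""))
    stop("measures must be a named list")
  ids <- meta$participant_id
  for (m in names(measures)) {
    if (!inherits(measures[[m]], "measure_features"))
      stop("measure ", m, " is not a measure_features object")
    if (!identical(measures[[m]]$subject_ids, as.character(ids)))
      stop("measure ", m, " rows are not aligned with meta")
  }
}

fold_confound <- function(measures, meta, rows_tr, rows_te, cfg, seed) {
  out_tr <- list(); out_te <- list()
  for (m in names(measures)) {
    Xtr <- subset_measure(measures[[m]], rows_tr)
    Xte <- subset_measure(measures[[m]], rows_te)
    if (cfg$confound == "fold") {
      # one restart and a modest iteration cap: this refits in every outer
      # fold, and the shared-kernel objective is smooth in 4 parameters
      mod <- fit_confound_model(Xtr, meta[rows_tr, , drop = FALSE],
                                seed = seed, restarts = 1, maxit = 150)
      Xtr <- residualize(Xtr, mod, meta[rows_tr, , drop = FALSE])
      Xte <- residualize(Xte, mod, meta[rows_te, , drop = FALSE])
    }
    out_tr[[m]] <- Xtr
    out_te[[m]] <- Xte
  }
  list(train = out_tr, test = out_te)
}

#' Cross-validated evaluation of the (fused) classifier
#'
#' Outer stratified k-fold evaluation. Within each training fold the
#' pipeline is: confound fit/removal (per `cfg$confound`), per-measure
#' soft-margin selection by inner stratified CV, (combined mode) integer
#' soft-voting coefficient selection on cached inner out-of-fold
#' probabilities, refit of every per-measure SVM on the full training
#' fold, and a single evaluation pass on the held-out fold. Per-measure
#' sign predictions are evaluated alongside the fused soft vote, so one
#' combined run also yields every single-measure result.
#'
#' @param measures named list of row-aligned [measure_features()].
#' @param meta metadata data.frame (`participant_id`, `group`, `age`,
#'   `sex`, optionally `site`), rows aligned with the measures.
#' @param cfg a [classifier_config()].
#' @param mode `"combined"` (soft-voting fusion) or `"single_measure"`.
#' @param fold_strata optional factor for outer-fold stratification
#'   (defaults to the group labels; pass `interaction(site, group)` for
#'   site-stratified folds).
#' @return Object of class `ensemble_result`.
#' @export
run_cv <- function(measures, meta, cfg = classifier_config(),
                   mode = c("combined", "single_measure"),
                   fold_strata = NULL) {
  mode <- match.arg(mode)
  check_alignment(measures, meta)
  y <- as.character(meta$group)
  if (length(unique(y)) < 2) stop("run_cv: both groups required")
  M <- length(measures)
  if (mode == "single_measure" && M != 1)
    stop("run_cv: single_measure mode expects exactly one measure")
  k <- min(cfg$outer_folds, min(table(y)))
  if (k < cfg$outer_folds)
    warning("run_cv: outer folds reduced to ", k)
  strata <- fold_strata %||% y
  folds <- stratified_folds(strata, k, child_seed(cfg$seed, 71L))

  if (cfg$confound == "whole_sample") {
    measures <- lapply(measures, function(X) {
      mod <- fit_confound_model(X, meta, seed = child_seed(cfg$seed, 72L))
      residualize(X, mod, meta)
    })
  }

  fold_rows <- vector("list", k)
  sel_C <- matrix(NA_real_, k, M, dimnames = list(NULL, names(measures)))
  coeffs <- matrix(1L, k, M, dimnames = list(NULL, names(measures)))
  weights <- vector("list", k)
  fm <- matrix(NA_real_, k, 3)
  pm <- lapply(names(measures), function(m) matrix(NA_real_, k, 3))
  names(pm) <- names(measures)

  for (f in seq_len(k)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2)
      stop("run_cv: fold ", f, " lacks a class; use fewer folds")
    fc <- fold_confound(measures, meta, tr, te, cfg,
                        child_seed(cfg$seed, 73L, f))
    y_tr <- y[tr]; y_te <- y[te]
    P_oof <- matrix(NA_real_, length(tr), M)
    ki <- min(cfg$inner_folds, min(table(y_tr)))
    inner_folds <- stratified_folds(y_tr, ki, child_seed(cfg$seed, 77L, f))
    probs_te <- matrix(NA_real_, length(te), M)
    labels_te <- matrix(NA_character_, length(te), M)
    weights[[f]] <- list()
    for (mi in seq_len(M)) {
      m <- names(measures)[mi]
      Xtr <- fc$train[[m]]$matrix
      Xte <- fc$test[[m]]$matrix
      sel <- select_C(Xtr, y_tr, cfg, seed = child_seed(cfg$seed, 74L,
                                                        f, mi),
                      folds = inner_folds)
      sel_C[f, mi] <- sel$C
      if (mode == "combined" && M > 1)
        P_oof[, mi] <- oof_probabilities(Xtr, y_tr, sel$C, inner_folds,
                                         child_seed(cfg$seed, 75L, f, mi))
      fit <- train_calibrated_svm(Xtr, y_tr, sel$C,
                                  seed = child_seed(cfg$seed, 76L, f, mi))
      pr <- predict(fit, Xte)
      probs_te[, mi] <- pr$prob_patient
      labels_te[, mi] <- pr$label
      weights[[f]][[m]] <- fit$w
      pm[[m]][f, ] <- balanced_metrics(y_te, pr$label)
    }
    if (mode == "combined" && M > 1) {
      co <- select_coefficients(P_oof, inner_folds, y_tr, cfg)
      coeffs[f, ] <- co
      fused <- soft_vote(probs_te, co)
      fm[f, ] <- balanced_metrics(y_te, fused$label)
    } else {
      fm[f, ] <- pm[[1]][f, ]
    }
    fold_rows[[f]] <- te
  }
  per_measure <- lapply(pm, function(mmat) {
    list(fold = data.frame(fold = seq_len(k), bac = mmat[, 1],
                           sen = mmat[, 2], spec = mmat[, 3]),
         mean_bac = mean(mmat[, 1]), mean_sen = mean(mmat[, 2]),
         mean_spec = mean(mmat[, 3]))
  })
  structure(list(
    fold = data.frame(fold = seq_len(k), bac = fm[, 1], sen = fm[, 2],
                      spec = fm[, 3]),
    mean_bac = mean(fm[, 1]), mean_sen = mean(fm[, 2]),
    mean_spec = mean(fm[, 3]),
    selected_C = sel_C, coefficients = coeffs, weights = weights,
    per_measure = per_measure, folds = folds, fold_rows = fold_rows,
    mode = mode, measures = names(measures), cfg = cfg, p_value = NULL),
    class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %s over %s: BAC %.2f%%, SEN %.2f%%, SPEC %.2f%%\n",
              x$mode, paste(x$measures, collapse = "+"),
              x$mean_bac, x$mean_sen, x$mean_spec))
  if (!is.null(x$p_value)) cat(sprintf("  permutation p = %.4g\n",
                                       x$p_value))
  invisible(x)
}

#' Permutation test of the cross-validated balanced accuracy
#'
#' Re-runs the whole training process (confound fit, nested selection of C
#' and coefficients, refits) on label-permuted data, with outer folds
#' re-seeded per replicate, and reports
#' `p = #(permuted mean BAC > observed mean BAC) / n_permutations`
#' (strict inequality). `conservative = TRUE` uses `(b + 1) / (n + 1)`
#' instead.
#'
#' @inheritParams run_cv
#' @param conservative use the add-one formula (default `FALSE`).
#' @return List: `p_value`, `observed` (the observed `ensemble_result`),
#'   `perm_bac` (null distribution of mean BAC).
#' @export
permutation_test <- function(measures, meta, cfg = classifier_config(),
                             mode = "combined", fold_strata = NULL,
                             conservative = FALSE) {
  B <- cfg$n_permutations
  if (B < 1) stop("permutation_test: n_permutations must be >= 1")
  obs <- run_cv(measures, meta, cfg, mode, fold_strata)
  perm_bac <- numeric(B)
  for (b in seq_len(B)) {
    meta_b <- meta
    meta_b$group <- with_seed(child_seed(cfg$seed, 500L, b),
                              sample(meta$group))
    cfg_b <- cfg
    cfg_b$seed <- child_seed(cfg$seed, 900L, b)
    perm_bac[b] <- run_cv(measures, meta_b, cfg_b, mode,
                          fold_strata)$mean_bac
  }
  p <- if (conservative) (sum(perm_bac > obs$mean_bac) + 1) / (B + 1)
       else sum(perm_bac > obs$mean_bac) / B
  list(p_value = p, observed = obs, perm_bac = perm_bac)
}

#' Pooled and site-stratified evaluation of a multi-site sample
#'
#' `pooled` concatenates all sites and runs plain group-stratified CV;
#' `stratified` stratifies the outer folds jointly on site and group so
#' every fold mirrors the site composition (sites smaller than the fold
#' count trigger a warning and spread over fewer folds).
#'
#' @inheritParams run_cv
#' @return List of two [run_cv()] results: `pooled`, `stratified`.
#' @export
evaluate_pooled_and_stratified <- function(measures, meta,
                                           cfg = classifier_config(),
                                           mode = "combined") {
  if (length(unique(meta$site)) < 2)
    warning("evaluate_pooled_and_stratified: single site; pooled and ",
            "stratified reduce to plain cross-validation")
  k <- min(cfg$outer_folds, min(table(meta$group)))
  if (any(table(meta$site, meta$group) < k))
    warning("evaluate_pooled_and_stratified: a site*group stratum is ",
            "smaller than the fold count; such folds merge its members")
  list(pooled = run_cv(measures, meta, cfg, mode),
       stratified = run_cv(measures, meta, cfg, mode,
                           fold_strata = interaction(meta$site,
                                                     meta$group)))
}

#' Train on one site, test on another
#'
#' The entire pipeline (confound model, per-measure C, soft-voting
#' coefficients) is tuned by nested CV within the training site only; the
#' fitted ensemble is then applied once to the full test site.
#'
#' @param train_measures,train_meta training-site features and metadata.
#' @param test_measures,test_meta test-site features and metadata
#'   (identical feature spaces).
#' @param cfg a [classifier_config()].
#' @param mode `"combined"` or `"single_measure"`.
#' @return List: `bac`, `sen`, `spec`, `selected_C`, `coefficients`.
#' @export
cross_site <- function(train_measures, train_meta, test_measures,
                       test_meta, cfg = classifier_config(),
                       mode = c("combined", "single_measure")) {
  mode <- match.arg(mode)
  check_alignment(train_measures, train_meta)
  check_alignment(test_measures, test_meta)
  if (!identical(names(train_measures), names(test_measures)))
    stop("cross_site: measure sets differ between sites")
  for (m in names(train_measures))
    if (ncol(train_measures[[m]]$matrix) != ncol(test_measures[[m]]$matrix))
      stop("cross_site: feature dimension mismatch in measure ", m)
  y_tr <- as.character(train_meta$group)
  y_te <- as.character(test_meta$group)
  M <- length(train_measures)
  if (cfg$confound %in% c("fold", "whole_sample")) {
    for (m in names(train_measures)) {
      mod <- fit_confound_model(train_measures[[m]], train_meta,
                                seed = child_seed(cfg$seed, 81L))
      train_measures[[m]] <- residualize(train_measures[[m]], mod,
                                         train_meta)
      test_measures[[m]] <- residualize(test_measures[[m]], mod,
                                        test_meta)
    }
  }
  sel_C <- numeric(M)
  probs_te <- matrix(NA_real_, length(y_te), M)
  labels_te <- matrix(NA_character_, length(y_te), M)
  P_oof <- matrix(NA_real_, length(y_tr), M)
  inner_folds <- NULL
  for (mi in seq_len(M)) {
    m <- names(train_measures)[mi]
    Xtr <- train_measures[[m]]$matrix
    sel <- select_C(Xtr, y_tr, cfg, seed = child_seed(cfg$seed, 82L, mi))
    sel_C[mi] <- sel$C
    if (mode == "combined" && M > 1) {
      P_oof[, mi] <- oof_probabilities(Xtr, y_tr, sel$C, sel$folds,
                                       child_seed(cfg$seed, 83L, mi))
      inner_folds <- sel$folds
    }
    fit <- train_calibrated_svm(Xtr, y_tr, sel$C,
                                seed = child_seed(cfg$seed, 84L, mi))
    pr <- predict(fit, test_measures[[m]]$matrix)
    probs_te[, mi] <- pr$prob_patient
    labels_te[, mi] <- pr$label
  }
  co <- rep(1L, M)
  if (mode == "combined" && M > 1) {
    co <- select_coefficients(P_oof, inner_folds, y_tr, cfg)
    pred <- soft_vote(probs_te, co)$label
  } else {
    pred <- labels_te[, 1]
  }
  met <- balanced_metrics(y_te, pred)
  list(bac = met[["bac"]], sen = met[["sen"]], spec = met[["spec"]],
       selected_C = stats::setNames(sel_C, names(train_measures)),
       coefficients = stats::setNames(co, names(train_measures)))
}
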