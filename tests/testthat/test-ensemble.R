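test_that("balanced_metrics follows the patient-positive convention", {
  y <- rep(c("patient", "control"), c(6, 4))
  expect_equal(balanced_metrics(y, y), c(bac = 100, sen = 100, spec = 100))
  allc <- rep("control", 10)
  expect_equal(balanced_metrics(y, allc), c(bac = 50, sen = 0, spec = 100))
  expect_error(balanced_metrics(rep("patient", 5), rep("patient", 5)),
               "both classes")
  # reporting arithmetic: SEN 85.83, SPEC 100.00 -> BAC 92.92 at 2 dp,
  # rounding half away from zero
  expect_equal(neurofuse:::round_half_up((85.83 + 100) / 2), 92.92)
  expect_equal(neurofuse:::round_half_up(2.675), 2.68) # not banker's
})

test_that("train_calibrated_svm separates, calibrates, and is symmetric", {
  set.seed(50)
  X <- rbind(matrix(rnorm(40, 2), 20), matrix(rnorm(40, -2), 20))
  y <- rep(c("patient", "control"), each = 20)
  fit <- train_calibrated_svm(X, y, C = 1, seed = 1)
  pr <- predict(fit, X)
  expect_equal(mean(pr$label == y), 1)
  expect_equal(pr$prob_patient + pr$prob_control, rep(1, 40))
  expect_true(all(pr$prob_patient >= 0 & pr$prob_patient <= 1))
  # flipping all labels flips predictions on a symmetric toy set
  yf <- ifelse(y == "patient", "control", "patient")
  fit2 <- train_calibrated_svm(X, yf, C = 1, seed = 1)
  pr2 <- predict(fit2, X)
  expect_equal(pr2$label, ifelse(pr$label == "patient", "control",
                                 "patient"))
  # constant columns tolerated
  fit3 <- train_calibrated_svm(cbind(X, 7), y, C = 1, seed = 1)
  expect_equal(mean(predict(fit3, cbind(X, 7))$label == y), 1)
  expect_error(train_calibrated_svm(X, rep("patient", 40), 1),
               "both classes")
})

test_that("select_C stays on the grid and prefers small C under noise", {
  set.seed(51)
  X <- rbind(matrix(rnorm(60, 1), 30), matrix(rnorm(60, -1), 30))
  y <- rep(c("patient", "control"), each = 30)
  cfg <- classifier_config(inner_folds = 5, seed = 7)
  sel <- select_C(X, y, cfg)
  expect_true(sel$C %in% cfg$C_grid)
  # duplicated grid entries cannot change the winner (tie -> first/smallest)
  cfg_dup <- cfg
  cfg_dup$C_grid <- sort(c(cfg$C_grid, cfg$C_grid))
  expect_equal(select_C(X, y, cfg_dup)$C, sel$C)
  # heavy label noise favours small C
  small <- 0L
  for (r in 1:10) {
    set.seed(60 + r)
    n <- 60
    Xn <- matrix(rnorm(n * 5), n)
    yn <- ifelse(Xn[, 1] + rnorm(n, 0, 2) > 0, "patient", "control")
    if (min(table(yn)) < 10) next
    cfg$seed <- 60 + r
    if (select_C(Xn, yn, cfg)$C <= 1) small <- small + 1L
  }
  expect_gte(small, 8)
})

test_that("soft_vote implements coefficient-weighted averaging", {
  P <- cbind(a = c(0.9, 0.2, 0.6), b = c(0.8, 0.4, 0.3))
  even <- soft_vote(P, c(2, 2))
  expect_equal(even$score, rowMeans(P))
  # single measure: any coefficient gives the same labels
  expect_equal(soft_vote(P[, 1, drop = FALSE], 7)$label,
               ifelse(P[, 1] >= 0.5, "patient", "control"))
  # worked example: probs (0.6, 0.3), coeffs (3, 1) -> 0.525 -> patient
  sv <- soft_vote(matrix(c(0.6, 0.3), 1), c(3, 1))
  expect_equal(sv$score, 0.525)
  expect_equal(sv$label, "patient")
  expect_error(soft_vote(P, c(1, 2, 3)), "coefficients")
  expect_error(soft_vote(P, c(0, 1)), "positive")
})

test_that("coefficient selection works on cached probabilities", {
  cfg <- classifier_config(coeff_search = "full_grid", seed = 1)
  set.seed(70)
  n <- 60
  y <- rep(c("patient", "control"), each = 30)
  fold <- rep(1:5, 12)
  co_all <- replicate(20, {
    good <- ifelse(y == "patient", 0.7, 0.3) + rnorm(n, 0, 0.15)
    noise <- runif(n)
    P <- cbind(pmin(pmax(good, 0), 1), noise)
    select_coefficients(P, fold, y, cfg)
  })
  expect_true(all(co_all >= 1 & co_all <= 10))
  expect_gte(mean(co_all[1, ] >= co_all[2, ]), 0.8)

  # full grid on M = 2 equals a no-cache brute force over all pairs
  set.seed(71)
  good <- pmin(pmax(ifelse(y == "patient", .65, .35) + rnorm(n, 0, .2),
                    0), 1)
  other <- pmin(pmax(ifelse(y == "patient", .55, .45) + rnorm(n, 0, .2),
                     0), 1)
  P <- cbind(good, other)
  co <- select_coefficients(P, fold, y, cfg)
  best <- NULL; best_bac <- -1
  for (c1 in 1:10) for (c2 in 1:10) {
    b <- softvote_bac_oracle(P, c(c1, c2), y, fold)
    if (b > best_bac + 1e-12) { best_bac <- b; best <- c(c1, c2) }
  }
  expect_equal(co, best)
  # greedy is ascent: never worse than the all-ones start
  cfg_g <- cfg; cfg_g$coeff_search <- "greedy"
  co_g <- select_coefficients(P, fold, y, cfg_g)
  expect_gte(softvote_bac_oracle(P, co_g, y, fold),
             softvote_bac_oracle(P, c(1, 1), y, fold))
  expect_lte(softvote_bac_oracle(P, co_g, y, fold), best_bac + 1e-12)
  expect_error(select_coefficients(matrix(runif(n * 7), n), fold, y, cfg),
               "full_grid refused")
})

test_that("run_cv partitions subjects, is deterministic, and reports BAC
           identities", {
  meta <- null_meta(40, seed = 80)
  ms <- random_measures(40, list(A = 30, B = 25), meta$participant_id, 81)
  # add signal so results are not degenerate
  sig <- ifelse(meta$group == "patient", 1, -1)
  ms$A$matrix[, 1] <- ms$A$matrix[, 1] + sig
  ms$B$matrix[, 2] <- ms$B$matrix[, 2] + 0.5 * sig
  cfg <- classifier_config(outer_folds = 5, inner_folds = 3, seed = 13,
                           confound = "none")
  res <- run_cv(ms, meta, cfg, mode = "combined")
  expect_setequal(unlist(res$fold_rows), seq_len(40))
  expect_equal(sum(lengths(res$fold_rows)), 40)
  expect_equal(res$fold$bac, (res$fold$sen + res$fold$spec) / 2,
               tolerance = 1e-10)
  expect_true(all(res$selected_C %in% cfg$C_grid))
  expect_true(all(res$coefficients %in% 1:10))
  res2 <- run_cv(ms, meta, cfg, mode = "combined")
  expect_identical(res$fold, res2$fold)
  expect_identical(res$coefficients, res2$coefficients)
  expect_equal(res$mean_bac, mean(res$fold$bac))
  # per-measure results emitted alongside the fused ones
  expect_named(res$per_measure, c("A", "B"))
  # single-measure mode
  r1 <- run_cv(ms["A"], meta, cfg, mode = "single_measure")
  expect_equal(r1$mean_bac, r1$per_measure$A$mean_bac)
  expect_error(run_cv(ms, meta, cfg, mode = "single_measure"),
               "exactly one")
})

test_that("permutation_test uses the strict-inequality formula", {
  set.seed(90)
  n <- 24
  meta <- null_meta(n, seed = 90)
  X <- matrix(rnorm(n * 5), n)
  X[, 1] <- X[, 1] + ifelse(meta$group == "patient", 3, -3) # separable
  ms <- list(A = measure_features(X, "A", meta$participant_id))
  cfg <- classifier_config(outer_folds = 3, inner_folds = 3, seed = 17,
                           n_permutations = 9, confound = "none")
  pt <- permutation_test(ms, meta, cfg, mode = "single_measure")
  expect_equal(pt$observed$mean_bac, 100)
  expect_equal(pt$p_value, 0) # nothing strictly exceeds 100
  expect_true(all(pt$perm_bac >= 0 & pt$perm_bac <= 100))
  ptc <- permutation_test(ms, meta, cfg, mode = "single_measure",
                          conservative = TRUE)
  expect_equal(ptc$p_value, 1 / 10)
  cfg$n_permutations <- 0
  expect_error(permutation_test(ms, meta, cfg, mode = "single_measure"),
               "n_permutations")
})

test_that("pooled and site-stratified evaluation behave as specified", {
  meta <- null_meta(48, seed = 95)
  meta$site <- rep(c("A", "B"), each = 24) # orthogonal to the group labels
  ms <- random_measures(48, list(M1 = 20), meta$participant_id, 96)
  ms$M1$matrix[, 1] <- ms$M1$matrix[, 1] +
    ifelse(meta$group == "patient", 1.5, -1.5)
  cfg <- classifier_config(outer_folds = 4, inner_folds = 3, seed = 19,
                           confound = "none")
  both <- evaluate_pooled_and_stratified(ms, meta, cfg,
                                         mode = "single_measure")
  expect_s3_class(both$pooled, "ensemble_result")
  # every stratified fold contains every site
  for (f in seq_along(both$stratified$fold_rows))
    expect_setequal(unique(meta$site[both$stratified$fold_rows[[f]]]),
                    c("A", "B"))
  # pooled mode is plain run_cv
  expect_equal(both$pooled$mean_bac,
               run_cv(ms, meta, cfg, mode = "single_measure")$mean_bac)
  # with site offsets orthogonal to group, the pooled combined pipeline
  # stays calibrated. Nested CV on null data is finite-sample pessimistic
  # (hyperparameter selection + a dominant nuisance axis center it a few
  # points below chance at small n), so the calibration property is
  # evaluated at n = 96 where that bias has decayed; the fused mode is
  # the headline model this op reports.
  metaL <- null_meta(96, seed = 950)
  metaL$site <- rep(c("A", "B"), each = 48)
  bacs <- sapply(1:10, function(r) {
    msn <- random_measures(96, list(M1 = 20, M2 = 20, M3 = 15),
                           metaL$participant_id, 970 + r)
    for (m in names(msn))
      msn[[m]]$matrix <- msn[[m]]$matrix + ifelse(metaL$site == "A", 2, -2)
    cfg$seed <- 200 + r
    run_cv(msn, metaL, cfg, mode = "combined")$mean_bac
  })
  se <- sd(bacs) / sqrt(length(bacs))
  expect_lt(abs(mean(bacs) - 50), 3 * se + 1e-9)
})

test_that("cross_site tunes on the training site only and transfers", {
  set.seed(98)
  mk_site <- function(n, seed, shift = 0) {
    meta <- null_meta(n, seed = seed)
    X <- matrix(rnorm(n * 15), n)
    X[, 1:3] <- X[, 1:3] + ifelse(meta$group == "patient", 1.2, -1.2)
    X <- X + shift
    list(meta = meta,
         ms = list(M = measure_features(X, "M", meta$participant_id)))
  }
  cfg <- classifier_config(outer_folds = 4, inner_folds = 3, seed = 23,
                           confound = "none")
  a <- mk_site(40, 981)
  b <- mk_site(40, 982)
  # degenerate reuse: test site = train site, well above chance
  self <- cross_site(a$ms, a$meta, a$ms, a$meta, cfg,
                     mode = "single_measure")
  expect_gt(self$bac, 80)
  # identical-distribution sites transfer within a few points
  gaps <- sapply(1:10, function(r) {
    a <- mk_site(40, 2000 + r)
    b <- mk_site(40, 3000 + r)
    cfg$seed <- 2000 + r
    within <- run_cv(a$ms, a$meta, cfg, mode = "single_measure")$mean_bac
    cs <- cross_site(a$ms, a$meta, b$ms, b$meta, cfg,
                     mode = "single_measure")$bac
    within - cs
  })
  expect_lte(abs(median(gaps)), 5)
  bad <- list(M = measure_features(matrix(0, 40, 3), "M",
                                   b$meta$participant_id))
  expect_error(cross_site(a$ms, a$meta, bad, b$meta, cfg),
               "dimension mismatch")
})

test_that("combining partly independent signals beats the best single
           measure", {
  cfg <- classifier_config(outer_folds = 5, inner_folds = 3, seed = 29,
                           confound = "none")
  med <- replicate(10, NA_real_)
  gap <- numeric(10)
  for (r in 1:10) {
    meta <- null_meta(50, seed = 400 + r)
    set.seed(500 + r)
    sig <- ifelse(meta$group == "patient", 1, -1)
    ms <- list(
      A = measure_features(cbind(sig * 0.8 + rnorm(50, 0, 1.3),
                                 matrix(rnorm(50 * 10), 50)), "A",
                           meta$participant_id),
      B = measure_features(cbind(sig * 0.8 + rnorm(50, 0, 1.3),
                                 matrix(rnorm(50 * 10), 50)), "B",
                           meta$participant_id),
      C = measure_features(cbind(sig * 0.8 + rnorm(50, 0, 1.3),
                                 matrix(rnorm(50 * 10), 50)), "C",
                           meta$participant_id))
    cfg$seed <- 400 + r
    res <- run_cv(ms, meta, cfg, mode = "combined")
    best_single <- max(sapply(res$per_measure, `[[`, "mean_bac"))
    gap[r] <- res$mean_bac - best_single
  }
  expect_gte(median(gap), 0)
})
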