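test_that("framewise displacement follows the Power formula", {
  z <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(z), rep(0, 10))
  m <- z
  m[5:10, 1] <- 0.2 # a single 0.2 mm x-translation step at t = 5
  fd <- framewise_displacement(m)
  expect_equal(fd[5], 0.2)
  expect_equal(fd[-5], rep(0, 9))
  m2 <- z
  m2[7:10, 4] <- 0.01 # 0.01 rad step on a 50 mm sphere -> 0.5 mm
  expect_equal(framewise_displacement(m2, 50)[7], 0.5)
  m3 <- z; m3[2, 1] <- NA
  expect_error(framewise_displacement(m3), "non-finite")
})

test_that("butter_bandpass reproduces the reference design", {
  # frozen from scipy.signal.butter(4, [0.01, 0.08] / 0.25, 'bandpass')
  flt <- butter_bandpass(0.01, 0.08, 0.5, 4)
  b_ref <- c(0.0148267454787, 0, -0.0593069819147, 0, 0.0889604728721,
             0, -0.0593069819147, 0, 0.0148267454787)
  a_ref <- c(1, -5.34618420196, 12.7301322121, -17.8191260981,
             16.160648995, -9.74342907896, 3.80158880383,
             -0.875194560762, 0.0916606282728)
  expect_equal(flt$b, b_ref, tolerance = 1e-10)
  expect_equal(flt$a, a_ref, tolerance = 1e-10)
  expect_error(butter_bandpass(0.01, 0.3, 0.5), "Nyquist")
})

test_that("clean_bold enforces its pipeline contract", {
  atl <- fix_small_atlas()
  dims <- dim(atl$labels)
  Tn <- 70
  set.seed(20)
  # constant voxel series -> all-zero residuals
  arr <- array(1.7, c(dims, Tn))
  b <- bold_series(arr, 2, atl$mask)
  m0 <- matrix(0, Tn, 6)
  cl <- clean_bold(b, m0, cleaning_config(nuisance = character(0)), atl)
  expect_lt(max(abs(cl$bold$data)), 1e-10)
  expect_false(cl$excluded)
  expect_equal(dim(cl$bold$data)[4], Tn - 10)

  # out-of-band sine is attenuated: 0.2 Hz at tr = 2 (Nyquist 0.25)
  tvec <- (0:(Tn - 1)) * 2
  sine <- sin(2 * pi * 0.2 * tvec)
  arr2 <- array(rep(sine, each = prod(dims)), c(dims, Tn))
  cl2 <- clean_bold(bold_series(arr2, 2, atl$mask), m0,
                    cleaning_config(nuisance = character(0)), atl)
  X <- neurofuse:::bold_matrix(cl2$bold)
  inpow <- var(sine[-(1:10)])
  # in-band (= total surviving) power below 5% of input power
  expect_lt(max(apply(X, 2, var)) / inpow, 0.05)

  # gross motion raises the exclusion flag but cleaning still runs
  m_bad <- m0; m_bad[30, 2] <- 2.0
  expect_true(clean_bold(b, m_bad, cleaning_config(), atl)$excluded)
  m_rot <- m0; m_rot[25, 5] <- 2 * pi / 180 # 2 degrees
  expect_true(clean_bold(b, m_rot, cleaning_config(), atl)$excluded)

  # FD-flagged volumes are censored
  m_sp <- m0; m_sp[40, 1] <- 0.8
  cl3 <- clean_bold(bold_series(array(rnorm(prod(dims) * Tn), c(dims, Tn)),
                                2, atl$mask), m_sp,
                    cleaning_config(), atl)
  expect_equal(cl3$n_censored, 2) # the spike flags t and t+1
  expect_equal(dim(cl3$bold$data)[4], Tn - 10 - 2)

  # too few surviving volumes
  expect_error(clean_bold(bold_series(arr[, , , 1:45, drop = FALSE], 2,
                                      atl$mask), m0[1:45, ],
                          cleaning_config(), atl), "insufficient volumes")
})

test_that("ReHo matches a brute-force Kendall's W and is in range", {
  set.seed(21)
  Tn <- 20
  X <- matrix(rnorm(Tn * 27), Tn)
  b <- matrix_as_bold(X, c(3, 3, 3))
  W <- reho_map(b, normalize = FALSE)
  # center voxel has the full 27-voxel neighbourhood
  expect_equal(W$data[2, 2, 2], kendall_w_bruteforce(X), tolerance = 1e-10)
  # a border voxel uses its available in-mask neighbours
  corner_cols <- which(apply(abs(sapply(1:27, function(v)
    arrayInd(v, c(3, 3, 3))) - c(1, 1, 1)) <= 1, 2, all))
  expect_equal(W$data[1, 1, 1],
               kendall_w_bruteforce(X[, corner_cols, drop = FALSE]),
               tolerance = 1e-10)
  expect_true(all(W$data >= 0 & W$data <= 1))
  # perfect concordance
  X2 <- matrix(rep(rnorm(Tn), 27), Tn)
  W2 <- reho_map(matrix_as_bold(X2, c(3, 3, 3)), normalize = FALSE)
  expect_equal(max(abs(W2$data - 1)), 0, tolerance = 1e-12)
  # normalization contract
  Wn <- reho_map(b)
  expect_equal(mean(Wn$data[Wn$mask]), 1, tolerance = 1e-10)
})

test_that("ALFF is linear in amplitude and confined to its band", {
  n <- 100; tr <- 2
  tvec <- (0:(n - 1)) * tr
  s1 <- sin(2 * pi * 0.05 * tvec)        # bin 10 exactly
  s2 <- 2 * s1
  s_out <- sin(2 * pi * 0.2 * tvec)      # bin 40 exactly, out of band
  X <- cbind(s1, s2, s_out, s1 + rnorm(n, 0, 1e-12))
  b <- matrix_as_bold(cbind(X, matrix(rnorm(n * 4), n)), c(2, 2, 2),
                      tr = tr)
  raw <- alff_map(b, normalize = FALSE)
  vals <- raw$data[raw$mask]
  expect_equal(vals[2] / vals[1], 2, tolerance = 1e-6)
  expect_lt(vals[3], 1e-6 * vals[1])
  norm <- alff_map(b)
  expect_equal(mean(norm$data[norm$mask]), 1, tolerance = 1e-10)
  expect_error(alff_map(matrix_as_bold(matrix(rnorm(8 * 4), 4), c(2, 2, 2),
                                       tr = 2)), "no frequency bin")
})

test_that("fc_matrix equals a brute-force correlation loop", {
  atl <- generate_atlas(c(8, 8, 8), R = 5, seed = 14)
  dims <- dim(atl$labels)
  set.seed(15)
  Tn <- 60
  arr <- array(rnorm(prod(dims) * Tn), c(dims, Tn))
  b <- bold_series(arr, 2, atl$mask)
  fc <- fc_matrix(b, atl)
  expect_identical(fc$values, t(fc$values))
  expect_true(all(diag(fc$values) == 1))
  X <- neurofuse:::bold_matrix(b)
  lab <- as.vector(atl$labels)[as.vector(atl$mask)]
  means <- sapply(1:5, function(r) rowMeans(X[, lab == r, drop = FALSE]))
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    expect_equal(fc$values[i, j], cor(means[, i], means[, j]),
                 tolerance = 1e-12)
  }
})

test_that("latent mixing yields the analytic inter-regional correlation", {
  # two regions sharing a latent with known mixing: rho = 0.6
  rho <- 0.6
  hits <- 0L
  for (r in 1:50) {
    set.seed(300 + r)
    Tn <- 120
    z <- matrix(rnorm(Tn * 2), Tn) %*% chol(matrix(c(1, rho, rho, 1), 2))
    m1 <- z[, 1] + rnorm(Tn, 0, 1e-8)
    m2 <- z[, 2] + rnorm(Tn, 0, 1e-8)
    if (abs(cor(m1, m2) - rho) <= 0.15) hits <- hits + 1L
  }
  expect_gte(hits, 45)
})

test_that("generator handles drive ReHo and ALFF monotonically", {
  atl <- fix_small_atlas()
  aff <- 1:2
  lev_reho <- matrix(NA_real_, 10, 3)
  lev_alff <- matrix(NA_real_, 10, 3)
  for (r in 1:10) {
    for (li in 1:3) {
      coh <- generate_cohort(
        2, atl, effect_spec(coherence_shift = c(0, 0.15, 0.3)[li],
                            amplitude_shift = c(1, 1.35, 1.7)[li],
                            affected_regions = aff),
        T = 80, tr = 2, modalities = "bold", seed = 4000 + r)
      fm <- suppressMessages(compute_measures(coh))
      pat <- fm$meta$group == "patient"
      lab <- as.vector(atl$labels)[as.vector(atl$mask)]
      lev_reho[r, li] <- mean(fm$measures$ReHo$matrix[pat, lab %in% aff])
      cfgu <- cleaning_config()
      cl <- clean_bold(coh$bold[[1]], coh$motion[[1]], cfgu, atl)
      raw_alff <- alff_map(cl$bold, normalize = FALSE)
      lev_alff[r, li] <- mean(raw_alff$data[atl$labels %in% aff])
    }
  }
  expect_true(all(diff(apply(lev_reho, 2, median)) > 0))
  expect_true(all(diff(apply(lev_alff, 2, median)) > 0))
})
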