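test_that("smooth_volume: identity, constants, and a convolution oracle", {
  set.seed(5)
  v <- voxel_volume(array(rnorm(9^3), c(9, 9, 9)),
                    voxel_size = c(1.5, 1.5, 1.5))
  expect_identical(smooth_volume(v, 0), v)

  const <- voxel_volume(array(2.5, c(9, 9, 9)), voxel_size = c(1.5, 1.5, 1.5))
  sm <- smooth_volume(const, 6)
  expect_lt(max(abs(sm$data - 2.5)), 1e-10)

  # impulse response against a dense convolution with the analytic
  # renormalized Gaussian kernel
  imp <- array(0, c(9, 9, 9))
  imp[5, 5, 5] <- 1
  vi <- voxel_volume(imp, voxel_size = c(1.5, 1.5, 1.5))
  out <- smooth_volume(vi, 6)
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 1.5
  r <- max(1L, ceiling(4 * sigma))
  k1 <- dnorm(seq(-r, r), sd = sigma)
  k1 <- k1 / sum(k1)
  dense <- array(0, c(9, 9, 9))
  norm <- array(0, c(9, 9, 9))
  for (i in 1:9) for (j in 1:9) for (k in 1:9) {
    acc <- 0; wacc <- 0
    for (di in -r:r) for (dj in -r:r) for (dk in -r:r) {
      w <- k1[di + r + 1] * k1[dj + r + 1] * k1[dk + r + 1]
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii >= 1 && ii <= 9 && jj >= 1 && jj <= 9 && kk >= 1 && kk <= 9) {
        acc <- acc + w * imp[ii, jj, kk]
        wacc <- wacc + w
      }
    }
    dense[i, j, k] <- acc / wacc
    norm[i, j, k] <- wacc
  }
  expect_lt(max(abs(out$data - dense)), 1e-12)
  expect_error(smooth_volume(voxel_volume(imp, voxel_size = c(0, 1, 1)), 6),
               "positive")
})

test_that("voxel_features flattens deterministically and invertibly", {
  set.seed(6)
  mask <- array(runif(5 * 4 * 3) < 0.6, c(5, 4, 3))
  mask[1, 1, 1] <- TRUE
  dat <- array(rnorm(60), c(5, 4, 3))
  v <- voxel_volume(dat, mask)
  f <- voxel_features(v)
  expect_length(f, sum(mask))
  expect_identical(voxel_features(voxel_volume(dat, mask)), f)
  # index-map round trip: refilling by mask order reproduces every voxel
  rec <- array(NA_real_, dim(mask))
  rec[mask] <- f
  expect_identical(rec[mask], dat[mask])
  for (i in 1:5) for (j in 1:4) for (k in 1:3)
    if (mask[i, j, k]) expect_identical(rec[i, j, k], dat[i, j, k])
})

test_that("region_density matches the closed-form KDE and normalizes", {
  atl <- structure(list(
    labels = array(c(rep(1L, 5), rep(2L, 5), rep(0L, 17)), c(3, 3, 3)),
    region_names = c("r1", "r2"), R = 2L,
    mask = array(c(rep(TRUE, 10), rep(FALSE, 17)), c(3, 3, 3)),
    voxel_size = c(3, 3, 3)), class = "brain_atlas")
  dat <- array(0, c(3, 3, 3))
  vals <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  dat[1:5] <- vals
  dat[6:10] <- vals + 0.3
  v <- voxel_volume(dat, atl$mask)
  rd <- region_density(v, atl, 1, grid_size = 128)
  bw <- silverman_oracle(vals)
  raw <- vapply(rd$grid[c(10, 60, 110)], kde_value_oracle, numeric(1),
                values = vals, bw = bw)
  # package pdf is renormalized to unit trapezoidal integral
  z <- neurofuse:::trapz_int(rd$grid, vapply(rd$grid, kde_value_oracle,
                                             numeric(1), values = vals,
                                             bw = bw))
  expect_equal(rd$pdf[c(10, 60, 110)], raw / z, tolerance = 1e-8)
  expect_equal(neurofuse:::trapz_int(rd$grid, rd$pdf), 1, tolerance = 1e-6)
  # degenerate region peaks at its value
  dat2 <- dat
  dat2[1:5] <- 0.7
  rd2 <- region_density(voxel_volume(dat2, atl$mask), atl, 1)
  expect_equal(rd2$grid[which.max(rd2$pdf)], 0.7, tolerance = 1e-3)
  expect_error(region_density(v, atl, 7), "region 7")
})

test_that("kl_similarity: identity, symmetry, Gaussian closed form", {
  g <- seq(-8, 9, length.out = 512)
  mk <- function(mu) structure(list(grid = g, pdf = dnorm(g, mu, 1),
                                    region = 1), class = "region_density")
  p <- mk(0); q <- mk(1)
  expect_identical(kl_similarity(p, p), 1)
  expect_identical(kl_similarity(p, q), kl_similarity(q, p))
  # KL(N(0,1) || N(1,1)) = 1/2 each way -> exp(-1)
  expect_equal(kl_similarity(p, q), exp(-1), tolerance = 2e-2)
  bad <- mk(0); bad$grid <- g + 0.1
  expect_error(kl_similarity(p, bad), "share")
})

test_that("morphological_network composes pairwise similarities", {
  atl <- generate_atlas(c(10, 10, 10), R = 3, seed = 6)
  set.seed(8)
  dat <- array(rnorm(1000, 0.5, 0.1), c(10, 10, 10))
  dat[atl$labels == 2] <- dat[atl$labels == 2] + 0.15
  v <- voxel_volume(dat, atl$mask)
  net <- morphological_network(v, atl, grid_size = 256)
  # oracle: R-level pairwise composition on the same pooled grids
  for (i in 1:2) for (j in (i + 1):3) {
    vi <- dat[atl$labels == i]
    vj <- dat[atl$labels == j]
    bwi <- silverman_oracle(vi)
    bwj <- silverman_oracle(vj)
    pad <- 3 * max(bwi, bwj)
    grid <- seq(min(vi, vj) - pad, max(vi, vj) + pad, length.out = 256)
    s <- kl_similarity(region_density(v, atl, i, grid = grid),
                       region_density(v, atl, j, grid = grid))
    expect_equal(net$values[i, j], s, tolerance = 1e-10)
  }
  # all-identical distributions give an all-ones matrix
  same <- voxel_volume(array(0.4, c(10, 10, 10)), atl$mask)
  net1 <- morphological_network(same, atl, grid_size = 128)
  expect_equal(max(abs(net1$values - 1)), 0)
})

test_that("morphological networks are equivariant and well-behaved", {
  atl <- generate_atlas(c(10, 10, 10), R = 4, seed = 9)
  set.seed(10)
  dat <- array(rnorm(1000, 0.5, 0.08), c(10, 10, 10))
  v <- voxel_volume(dat, atl$mask)
  net <- morphological_network(v, atl, grid_size = 256)
  # relabelling regions permutes rows/columns identically
  perm <- c(3L, 1L, 4L, 2L)
  atl2 <- atl
  atl2$labels[atl$labels > 0] <- perm[atl$labels[atl$labels > 0]]
  net2 <- morphological_network(v, atl2, grid_size = 256)
  expect_equal(net2$values[perm, perm], net$values, ignore_attr = TRUE,
               tolerance = 1e-12)
  # type invariants over random subjects
  for (r in 1:25) {
    set.seed(100 + r)
    vr <- voxel_volume(array(rnorm(1000, 0.5, 0.1), c(10, 10, 10)),
                       atl$mask)
    nr <- morphological_network(vr, atl, grid_size = 128)$values
    expect_lt(max(abs(nr - t(nr))), 1e-12)
    expect_true(all(diag(nr) == 1))
    expect_true(all(nr > 0 & nr <= 1))
  }
})

test_that("similarity falls strictly with separation, invariant to affine", {
  atl <- generate_atlas(c(10, 10, 10), R = 2, seed = 12)
  set.seed(13)
  base <- array(rnorm(1000, 0.5, 0.1), c(10, 10, 10))
  sims <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(sh) {
    dat <- base
    dat[atl$labels == 2] <- dat[atl$labels == 2] + sh
    morphological_network(voxel_volume(dat, atl$mask), atl,
                          grid_size = 256)$values[1, 2]
  }, numeric(1))
  expect_true(all(diff(sims) < 0))
  # same affine transform of both regions leaves similarity unchanged
  dat <- base
  dat[atl$labels == 2] <- dat[atl$labels == 2] + 0.1
  s0 <- morphological_network(voxel_volume(dat, atl$mask), atl,
                              grid_size = 512)$values[1, 2]
  s1 <- morphological_network(voxel_volume(3 * dat - 1, atl$mask), atl,
                              grid_size = 512)$values[1, 2]
  expect_lt(abs(s1 - s0), 1e-3)
})

test_that("connectivity matrices round-trip through TSV", {
  atl <- generate_atlas(c(10, 10, 10), R = 3, seed = 21)
  set.seed(22)
  v <- voxel_volume(array(rnorm(1000, 0.5, 0.1), c(10, 10, 10)), atl$mask)
  net <- morphological_network(v, atl, grid_size = 128)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_conn_tsv(net, f)
  back <- read_conn_tsv(f, "morphological")
  expect_equal(back$values, net$values, tolerance = 1e-12)
  expect_identical(back$region_names, net$region_names)
  # vectorization order is the documented row-major upper triangle
  vec <- conn_vector(net)
  expect_identical(names(vec)[1], paste0(net$region_names[1], "--",
                                         net$region_names[2]))
  expect_equal(unname(vec),
               c(net$values[1, 2], net$values[1, 3], net$values[2, 3]))
  # unvectorize is the inverse
  m <- neurofuse:::unvectorize_conn(unname(vec), 3)
  expect_equal(m + diag(3), net$values, ignore_attr = TRUE)
})
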