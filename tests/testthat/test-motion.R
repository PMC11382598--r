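# enorm, outlier fractions, min-outlier selection, censoring and BC/AC
# distribution statistics.

test_that("enorm follows the forward-difference norm with per-run resets", {
  z <- matrix1D(matrix(0, 10, 6))
  expect_equal(computeEnorm(z), rep(0, 10))

  m <- matrix(0, 5, 6)
  m[3, 1] <- 0.3; m[3, 4] <- 0.4   # one step of (0.3, 0, 0, 0.4, 0, 0)
  expect_equal(computeEnorm(matrix1D(m))[3], 0.5)

  set.seed(42)
  mr <- matrix(rnorm(20 * 6), 20, 6)
  rl <- c(8L, 12L)
  got <- computeEnorm(matrix1D(mr), rl)
  # brute-force per-element loop oracle
  want <- numeric(20)
  starts <- c(1L, 9L)
  for (r in 1:2) for (t in seq_len(rl[r])) {
    g <- starts[r] + t - 1L
    if (t == 1L) want[g] <- 0
    else {
      s <- 0
      for (k in 1:6) s <- s + (mr[g, k] - mr[g - 1L, k])^2
      want[g] <- sqrt(s)
    }
  }
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(computeEnorm(matrix1D(mr[, 1:5])), "6 columns")
})

test_that("enorm ignores constant offsets in any parameter", {
  set.seed(7)
  m <- matrix(rnorm(30 * 6), 30, 6)
  shifted <- sweep(m, 2, c(5, -2, 0.4, 100, 3, 9), "+")
  expect_equal(computeEnorm(matrix1D(m)), computeEnorm(matrix1D(shifted)),
               tolerance = 1e-10)
})

test_that("outlier fraction is zero on constant data and finds injections", {
  const <- dataset4D(array(500, c(6, 6, 4, 30)), tr = 2)
  msk <- mask3D(array(1, c(6, 6, 4)))
  expect_equal(computeOutlierFraction(const, msk), rep(0, 30))
  expect_error(computeOutlierFraction(const, mask3D(array(0, c(6, 6, 4)))),
               "empty mask")

  # shift 10% of in-mask voxels by 20 noise sd at one volume
  set.seed(8)
  arr <- array(rnorm(12 * 12 * 6 * 60, 100, 5), c(12, 12, 6, 60))
  n <- 12 * 12 * 6
  hit <- sample(n, round(0.1 * n))
  vol <- arr[, , , 31]
  vol[hit] <- vol[hit] + 20 * 5
  arr[, , , 31] <- vol
  frac <- computeOutlierFraction(dataset4D(arr, tr = 2),
                                 mask3D(array(1, c(12, 12, 6))))
  expect_lt(abs(frac[31] - 0.10), 0.02)
  expect_lt(max(frac[-31]), 0.01)
})

test_that("outlier fraction matches a literal per-voxel loop oracle", {
  set.seed(9)
  arr <- array(rnorm(8 * 8 * 4 * 30, 0, 1), c(8, 8, 4, 30))
  arr[2, 3, 1, 12] <- 40
  arr[5, 5, 2, 4] <- -35
  ds <- dataset4D(arr, tr = 2)
  msk <- mask3D(array(1, c(8, 8, 4)))
  got <- computeOutlierFraction(ds, msk)

  ord <- 1L + floor(30 * 2 / 150)
  x <- seq(-1, 1, length.out = 30)
  B <- cbind(1, x)  # Legendre order 1 basis for this T
  if (ord >= 2) B <- cbind(B, (3 * x^2 - 1) / 2)
  thr_z <- qnorm(1 - 0.001 / (2 * 30))
  out <- matrix(FALSE, 30, 8 * 8 * 4)
  v <- 0L
  for (k in 1:4) for (j in 1:8) for (i in 1:8) {
    v <- v + 1L
    idx <- i + (j - 1) * 8 + (k - 1) * 64
    y <- arr[i, j, k, ]
    r <- resid(lm(y ~ B - 1))
    madn <- 1.4826 * median(abs(r))
    out[, idx] <- abs(r) > thr_z * madn
  }
  expect_equal(got, rowMeans(out), tolerance = 1e-12)
})

test_that("min-outlier volume selection honors ties and prefixes", {
  expect_identical(selectMinOutlierVolume(c(0.2, 0.0, 0.1)), 2L)
  expect_identical(selectMinOutlierVolume(c(0.1, 0.1)), 1L)
  expect_identical(selectMinOutlierVolume(c(0.0, 0.5, 0.2),
                                          censorable_prefix = 1L), 3L)
  # phantom with one clean volume among perturbed ones
  set.seed(10)
  arr <- array(rnorm(8 * 8 * 4 * 20, 100, 2), c(8, 8, 4, 20))
  for (t in setdiff(1:20, 13)) {
    hit <- sample(256, 26)
    vol <- arr[, , , t]; vol[hit] <- vol[hit] + 30; arr[, , , t] <- vol
  }
  frac <- computeOutlierFraction(dataset4D(arr, tr = 2),
                                 mask3D(array(1, c(8, 8, 4))))
  expect_identical(selectMinOutlierVolume(frac), 13L)
})

test_that("censor rule and previous-volume extension match a loop oracle", {
  en <- rep(0.1, 12); of <- rep(0.01, 12)
  expect_equal(buildCensor(en, of)@keep, rep(1, 12))

  en2 <- rep(0, 12); en2[8] <- 0.5
  cv <- buildCensor(en2, of, enorm_limit = 0.3)
  expect_identical(which(cv@keep == 0), c(7L, 8L))

  expect_error(buildCensor(en, of, enorm_limit = 0), "positive")

  set.seed(11)
  enr <- runif(40, 0, 0.6); ofr <- runif(40, 0, 0.1)
  rl <- c(25L, 15L)
  cvr <- buildCensor(enr, ofr, 0.3, 0.05, TRUE, rl)
  keep <- rep(TRUE, 40)
  starts <- c(1L, 26L)
  for (r in 1:2) for (t in seq_len(rl[r])) {
    g <- starts[r] + t - 1L
    if (enr[g] > 0.3) {
      keep[g] <- FALSE
      if (t > 1L) keep[g - 1L] <- FALSE
    }
    if (ofr[g] > 0.05) keep[g] <- FALSE
  }
  expect_equal(cvr@keep, as.numeric(keep))
})

test_that("censor summary reproduces printed review arithmetic", {
  keep <- rep(1, 242); keep[c(10, 11, 100)] <- 0
  cs <- censorSummary(censorVector(keep), 242L)
  expect_equal(cs[["censor fraction"]], 0.012397)
  expect_equal(cs[["fraction censored per run"]], 0.0123967)
  expect_equal(cs[["TRs censored"]], 3)
  expect_equal(cs[["num TRs per run (applied)"]], 239)
  expect_equal(cs[["TRs total (uncensored)"]], 242)

  cs0 <- censorSummary(censorVector(rep(1, 100)))
  expect_equal(cs0[["censor fraction"]], 0)
  csa <- censorSummary(censorVector(rep(0, 50)))
  expect_equal(csa[["censor fraction"]], 1)
  expect_equal(csa[["num TRs per run (applied)"]], 0)
})

test_that("BC/AC distribution stats honor censoring and interpolation", {
  cv <- censorVector(rep(1, 5))
  s <- distributionStats(rep(3.3, 5), cv)
  expect_equal(unlist(s$bc), c(min = 3.3, q25 = 3.3, median = 3.3,
                               q75 = 3.3, max = 3.3))

  cv100 <- censorVector(rep(1, 100))
  expect_equal(distributionStats(1:100, cv100)$bc$median, 50.5)

  # censoring the top decile lowers AC max to the 90th order statistic
  x <- sample(1:100)
  keep <- as.numeric(!(x > 90))
  s2 <- distributionStats(x, censorVector(keep))
  expect_equal(s2$ac$max, 90)
  expect_equal(s2$bc$max, 100)

  s3 <- distributionStats(1:4, censorVector(rep(0, 4)))
  expect_false(s3$ac_defined)
  expect_true(is.na(s3$ac$median))
})

test_that("default-limit censoring equals the generator's truth record", {
  spec <- simSpec(seed = 31L, presteady_n = 2L,
                  motion_spike_times = c(45L, 120L),
                  motion_spike_magnitudes = c(1.0, 0.7),
                  networks = list(),
                  variance_lines = data.frame(i = integer(), j = integer(),
                                              scale = numeric()))
  sim <- simulateEpi(spec)
  en <- computeEnorm(sim$truth$motion, runLengths(sim$epi))
  of <- computeOutlierFraction(sim$epi, sim$mask)
  cv <- buildCensor(en, of, run_lengths = runLengths(sim$epi))
  expect_identical(which(cv@keep == 0), sim$truth$expected_censored)
})
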