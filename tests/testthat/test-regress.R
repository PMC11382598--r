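# Ideal responses, bandpass DF cost, DF accounting, per-stimulus censor
# fractions, and design-matrix collinearity.

test_that("ideal responses convolve, sum, and expose duplicate timing", {
  # instantaneous event with the identity kernel: a shifted unit pulse
  ir <- buildIdealResponse(list(10), list(0.1), "identity", tr = 2,
                           n_volumes = 20)
  expect_equal(which(ir$series[, 1] > 0.5), 6L)  # onset 10 s = volume 6
  expect_equal(sum(ir$series[, 1] > 1e-8), 1L)

  ir2 <- buildIdealResponse(list(c(4, 20), c(10, 30)), list(6, 6), "gamma",
                            tr = 2, n_volumes = 30)
  expect_equal(ir2$sum, rowSums(ir2$series))
  expect_equal(max(ir2$series), 1, tolerance = 0.01)   # unit-peak kernel,
  # sampled at the TR grid (the exact peak can fall between samples)

  # the same timing file entered twice: perfectly collinear columns
  dup <- buildIdealResponse(list(c(4, 20), c(4, 20)), list(6, 6), "gamma",
                            tr = 2, n_volumes = 30)
  expect_equal(cor(dup$series[, 1], dup$series[, 2]), 1, tolerance = 1e-12)
  items <- cormatWarnings(matrix1D(dup$series, c("a", "b")))
  expect_length(items, 1L)
  expect_equal(as.character(items[[1]]$level), "severe")

  expect_error(buildIdealResponse(list(1000), list(1), "gamma", tr = 2,
                                  n_volumes = 20), "beyond run end")
})

test_that("bandpass regressor count matches brute-force DFT enumeration", {
  # T=200, TR=2, band 0.01-0.1 Hz
  got <- countBandpassRegressors(200, 2, c(0.01, 0.1))
  k <- 1:100
  f <- k / 400
  out <- f < 0.01 | f > 0.1
  want <- sum(ifelse(k == 100, 1, 2)[out])
  expect_identical(got, as.integer(want))
  expect_identical(got, 125L)          # 62.5% of 200

  # full-band pass removes nothing
  expect_identical(countBandpassRegressors(200, 2, c(1e-9, 0.25)), 0L)
  expect_error(countBandpassRegressors(200, 2, c(0.1, 0.5)), "Nyquist")
})

test_that("LFF bandpass consumes ~60% of DFs at TR=2 and ~80% at TR=1", {
  # "almost 60%" / "nearly 80%": the exact count sits within a point or two
  # of those figures for any realistic run length
  for (T in c(100, 250, 500, 750, 1000)) {
    expect_gte(countBandpassRegressors(T, 2, c(0.01, 0.1)) / T, 0.59)
    expect_gte(countBandpassRegressors(T, 1, c(0.01, 0.1)) / T, 0.78)
  }
})

test_that("bandpass cost converges to the band-fraction limit", {
  T <- 10000
  frac <- countBandpassRegressors(T, 2, c(0.01, 0.1)) / T
  limit <- 1 - (0.1 - 0.01) / 0.25
  expect_lt(abs(frac - limit) / limit, 0.01)
  # nonincreasing in band width
  f1 <- countBandpassRegressors(400, 2, c(0.01, 0.05))
  f2 <- countBandpassRegressors(400, 2, c(0.01, 0.1))
  f3 <- countBandpassRegressors(400, 2, c(0.005, 0.2))
  expect_gte(f1, f2); expect_gte(f2, f3)
})

test_that("DF accounting reproduces the review identity and conserves", {
  df <- dfAccounting(242, 3, n_motion = 6, n_drift = 3, n_stim = 4)
  expect_identical(df$left, 226)
  expect_equal(df$final_fraction, 226 / 242)
  expect_equal(signif(df$final_fraction, 6), 0.933884)

  expect_equal(dfAccounting(100)$final_fraction, 1)

  set.seed(19)
  for (i in 1:25) {
    T <- sample(50:500, 1)
    parts <- rmultinom(1, sample(0:T, 1), rep(1, 5))[, 1]
    d <- dfAccounting(T, parts[1], parts[2], parts[3], parts[4], parts[5])
    expect_identical(d$total, T)
    expect_identical(d$censored + d$used_by_regressors + d$left, T)
  }

  over <- dfAccounting(20, 10, n_motion = 15)
  expect_identical(over$left, 0L)
  expect_equal(as.character(over$warn$level), "severe")
})

test_that("per-stimulus censor fractions reproduce printed review values", {
  # 136 response TRs with 2 censored -> 0.015
  ser <- matrix(0, 242, 2)
  ser[1:136, 1] <- 1
  ser[10:219, 2] <- 1   # 210 response TRs
  ideal <- structure(list(series = ser, sum = rowSums(ser),
                          labels = c("vis", "aud")), class = "IdealResponse")
  keep <- rep(1, 242); keep[c(5, 60)] <- 0
  scf <- stimCensorFractions(ideal, censorVector(keep))
  expect_equal(scf$n_response, c(136L, 210L))
  expect_equal(scf$n_censored, c(2L, 1L))   # volume 5 precedes stim 2's window
  expect_equal(scf$fraction[1], 0.015)

  scf0 <- stimCensorFractions(ideal, censorVector(rep(1, 242)))
  expect_equal(scf0$fraction, c(0, 0))

  keep_all <- rep(1, 242); keep_all[1:136] <- 0
  scf1 <- stimCensorFractions(ideal, censorVector(keep_all))
  expect_equal(scf1$fraction[1], 1)
  expect_true(any(vapply(scf1$warns, function(w)
    as.character(w$level) == "severe", logical(1))))

  empty <- structure(list(series = cbind(ser[, 1], 0), sum = ser[, 1],
                          labels = c("a", "b")), class = "IdealResponse")
  scfe <- stimCensorFractions(empty, censorVector(rep(1, 242)))
  expect_true(is.na(scfe$fraction[2]))
})

test_that("collinearity warnings equal a double-loop oracle", {
  set.seed(20)
  X <- matrix(rnorm(60 * 6), 60, 6)
  X[, 4] <- X[, 1] * 0.9 + rnorm(60, 0, 0.1)   # strongly correlated pair
  X[, 5] <- X[, 2] + rnorm(60, 0, 0.8)          # mildly correlated
  items <- cormatWarnings(matrix1D(X))
  oracle <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    r <- abs(naive_cor(X[, i], X[, j]))
    if (r >= 0.4) oracle[[length(oracle) + 1L]] <- c(i, j, r)
  }
  expect_length(items, length(oracle))
  got_pairs <- t(vapply(items, function(it)
    c(it$payload$i, it$payload$j), numeric(2)))
  want_pairs <- t(vapply(oracle, function(o) o[1:2], numeric(2)))
  expect_equal(got_pairs[order(got_pairs[, 1], got_pairs[, 2]), , drop = FALSE],
               want_pairs[order(want_pairs[, 1], want_pairs[, 2]), ,
                          drop = FALSE])

  orth <- cbind(sin(1:50), cos(1:50))
  expect_length(cormatWarnings(matrix1D(orth)), 0L)

  const <- cbind(rnorm(30), rep(2, 30))
  itc <- cormatWarnings(matrix1D(const))
  expect_true(any(grepl("constant", vapply(itc, `[[`, "", "name"))))
})
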