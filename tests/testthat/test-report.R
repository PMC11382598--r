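# Montage slice selection, alpha thresholding, grayplot, edge overlays,
# report assembly, and ratings.

test_that("montage slices stay inside the automask extent", {
  u <- dataset3D(array(7, c(20, 20, 16)))
  sl <- selectMontageSlices(u, 3, 4)
  expect_equal(sl$indices, round(seq(1, 16, length.out = 6)[2:5]))

  # object occupying the middle half of z
  v <- array(0, c(20, 20, 16)); v[, , 5:12] <- 100
  sl2 <- selectMontageSlices(dataset3D(v), 3, 5)
  expect_true(all(sl2$indices >= 5 & sl2$indices <= 12))

  sl3 <- selectMontageSlices(dataset3D(v), 3, 1)
  expect_equal(sl3$indices, round((5 + 12) / 2))

  expect_warning(selectMontageSlices(dataset3D(array(0, c(8, 8, 8))), 3, 2),
                 "automask")
})

test_that("alpha fade is quadratic, continuous, and boxed", {
  ov <- array(0, c(8, 8, 4))
  ov[4, 4, 2] <- 2; ov[5, 4, 2] <- 1; ov[6, 4, 2] <- -3
  at <- applyAlphaThreshold(ov, 2)
  expect_equal(at$alpha[5, 4, 2], 0.25)        # |v| = thr/2 -> 0.25
  expect_equal(at$alpha[4, 4, 2], 1)
  expect_equal(at$alpha[6, 4, 2], 1)           # two-sided
  expect_true(at$outline[4, 4, 2])
  expect_error(applyAlphaThreshold(ov, 0), "positive")

  # continuity and monotonicity in |v|
  vs <- seq(0, 4, by = 0.01)
  al <- pmin((vs / 2)^2, 1)
  expect_true(all(diff(al) >= 0))
  expect_equal(al[vs == 2], 1)

  # default t threshold at p = 0.001 two-sided, DF = 226, vs a
  # distribution-function inversion oracle
  thr <- tStatThreshold(226)
  oracle <- uniroot(function(q) pt(q, 226) - (1 - 0.001 / 2),
                    c(0.1, 50), tol = 1e-10)$root
  expect_equal(thr, oracle, tolerance = 1e-6)
})

test_that("percentile display rules match a sort-based oracle", {
  set.seed(25)
  stat <- array(rchisq(16 * 16 * 8, 3), c(16, 16, 8))
  msk <- mask3D(array(rbinom(16 * 16 * 8, 1, 0.6), c(16, 16, 8)))
  pr <- percentileRange(stat, msk)
  v <- sort(stat[values(msk) > 0])
  n <- length(v)
  q90 <- v[floor((n - 1) * 0.90) + 1] +
    ((n - 1) * 0.90 - floor((n - 1) * 0.90)) *
    (v[min(n, floor((n - 1) * 0.90) + 2)] - v[floor((n - 1) * 0.90) + 1])
  expect_equal(pr$threshold, q90, tolerance = 1e-12)
  expect_gt(pr$max, pr$threshold)
})

test_that("grayplot clips at the p=0.001 normal quantile and orders clusters", {
  expect_equal(renderGrayplot(clean_sim()$epi, clean_sim()$mask)$zclip,
               3.2905, tolerance = 1e-4)

  # two-cluster phantom: rows of each cluster contiguous in the ordering
  set.seed(26)
  T <- 60; n <- 40
  c1 <- rnorm(T); c2 <- rnorm(T)
  Y <- matrix(rnorm(T * n, 0, 0.3), T, n)
  Y[, 1:20] <- Y[, 1:20] + 2 * c1
  Y[, 21:40] <- Y[, 21:40] + 2 * c2
  arr <- array(t(Y), c(5, 8, 1, T)) + 100
  gp <- renderGrayplot(dataset4D(arr, tr = 1), mask3D(array(1, c(5, 8, 1))))
  memb <- (gp$ordering <= 20)
  expect_lte(sum(diff(memb) != 0), 1L)   # one transition = contiguous blocks

  # permutation invariance of the pixel multiset
  expect_equal(sort(as.vector(gp$matrix)),
               sort(as.vector(gp$matrix[sample(nrow(gp$matrix)), ])))

  expect_error(renderGrayplot(dataset4D(array(1, c(3, 3, 1, 12)), tr = 1),
                              mask3D(array(1, c(3, 3, 1)))), "degenerate")
})

test_that("edge overlays trace boundaries and uniform volumes have none", {
  expect_false(any(edgeMask(array(5, c(10, 10, 8)))))

  ph <- makePhantomAnat(quiet_spec(seed = 62L))
  edges <- edgeMask(values(ph$anat))
  # edge voxels form a shell within one voxel of the analytic boundary
  dims <- dim(values(ph$anat))
  rho <- fmriqc:::.ellipsoid_rho(dims)
  # the outer boundary shell must be well covered by detected edges
  boundary_ring <- rho >= 0.93 & rho <= 1.07
  expect_gt(mean(edges[boundary_ring]), 0.5)

  img <- renderEdgeOverlay(ph$anat, ph$anat)
  expect_identical(dim(img$image)[3], 3L)
  img2 <- renderEdgeOverlay(ph$anat, ph$anat)
  expect_identical(img$image, img2$image)   # deterministic
})

test_that("report has all ten blocks in order, colored warns, and ratings", {
  sim <- default_sim()
  res <- memo_fixture("pipeline_res", function()
    runSubjectQc(sim$epi, sim$anat, sim$mask, sim$truth$motion,
                 atlas = makeToyAtlas(sim$mask, 4L),
                 stim_onsets = list(c(20, 120, 260), c(60, 200, 330)),
                 stim_durations = list(20, 20),
                 out_dir = file.path(tempdir(), "QC_t01"), subject = "t01"))
  dir <- res$report_dir
  html <- paste(readLines(file.path(dir, "index.html")), collapse = "\n")
  ids <- regmatches(html,
                    gregexpr("(?<=<section id=')[a-z0-9]+", html,
                             perl = TRUE))[[1]]
  expect_equal(ids, c("vorig", "ve2a", "va2t", "vstat", "mot", "mecho",
                      "regr", "radcor", "warns", "qsumm"))
  lvl <- as.character(maxWarnLevel(res$warn_items))
  expect_true(grepl(sprintf("data-warn-level='%s'", lvl), html))
  expect_true(grepl("multi-echo", html))           # mecho placeholder
  expect_true(grepl("censor fraction", html))      # qsumm embeds the dict
  # relocatable: no absolute paths in the page
  expect_false(grepl("src='/", html))
  expect_false(grepl(normalizePath(dir, winslash = "/"), html, fixed = TRUE))

  # ratings round trip and drive FINAL-based filtering
  rateBlock(dir, "t01", "FINAL", rating = "X")     # symbol accepted
  r <- readRatings(dir, "t01")
  expect_equal(r$FINAL$rating, "bad")
  rateBlock(dir, "t01", "radcor", comment = "patchy")
  expect_equal(readRatings(dir, "t01")$radcor$rating, "other")
  expect_error(rateBlock(dir, "t01", "nope", rating = "good"), "unknown")

  rd <- readReviewDict(file.path(dir, "out.ss_review.t01.json"), "json")
  other <- entries(rd); other[["FINAL rating"]] <- "none"
  tab <- buildGroupTable(list(rd, reviewDict(other)), c("t01", "t02"))
  out <- filterReport(tab, list(criterion("FINAL rating", "EQ", "bad")))
  expect_equal(out$subject, "t01")

  expect_equal(ratingSymbol("good"), "+")
  expect_equal(ratingSymbol("?"), "other")
})
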