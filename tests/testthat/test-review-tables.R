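# Review assembly, group tabulation, criterion filtering, and the header
# consistency scan.

make_dict <- function(...) reviewDict(list(...))

test_that("single-subject review merges fragments and keeps identities", {
  keep <- rep(1, 242); keep[c(3, 50, 51)] <- 0
  cv <- censorVector(keep)
  cs <- censorSummary(cv, 242L)
  df <- dfAccounting(242, 3, n_motion = 6, n_drift = 3, n_stim = 4)
  rev <- buildSsReview(cs, list(
    "degrees of freedom used" = df$used_by_regressors,
    "degrees of freedom left" = df$left))
  e <- entries(rev)
  expect_equal(e[["censor fraction"]], round(3 / 242, 6))
  expect_equal(e[["degrees of freedom used"]] +
                 e[["degrees of freedom left"]] + e[["TRs censored"]],
               e[["TRs total (uncensored)"]])

  # duplicate labels across fragments collide loudly
  expect_error(buildSsReview(cs, cs), "collision")

  # dialect round trip preserves equality
  pc <- withr::local_tempfile(); pj <- withr::local_tempfile()
  writeReviewDict(rev, pc, "colon"); writeReviewDict(rev, pj, "json")
  expect_equal(entries(readReviewDict(pc, "colon")),
               entries(readReviewDict(pj, "json")))
})

test_that("group tables keep first-seen column order and flag gaps", {
  d1 <- make_dict(a = 1, b = "x", c = 3)
  d2 <- make_dict(a = 2, d = 4)
  tab <- buildGroupTable(list(d1, d2), c("s1", "s2"))
  expect_equal(tab@labels, c("a", "b", "c", "d"))

  tab3 <- buildGroupTable(list(d1, d1, d1))
  expect_identical(length(tab3@subjects), 3L)

  p <- withr::local_tempfile(fileext = ".tsv")
  writeGroupTable(tab, p)
  lines <- readLines(p)
  expect_equal(lines[1], "subject\ta\tb\tc\td")
  expect_equal(strsplit(lines[3], "\t")[[1]],
               c("s2", "2", "NA", "NA", "4"))

  # column order equals first-seen order under permuted input
  set.seed(23)
  dicts <- list(make_dict(x = 1, y = 2), make_dict(z = 3, x = 1),
                make_dict(w = 0, y = 5))
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    tabp <- buildGroupTable(dicts[perm])
    want <- character()
    for (d in dicts[perm]) want <- c(want, setdiff(names(entries(d)), want))
    expect_equal(tabp@labels, want)
  }
})

test_that("filter criteria match their documented semantics", {
  tab <- buildGroupTable(list(make_dict(`TSNR average` = 150,
                                        `flip guess` = "NO_FLIP"),
                              make_dict(`TSNR average` = 90,
                                        `flip guess` = "DO_FLIP")),
                         c("A", "B"))
  lt <- filterReport(tab, list(criterion("TSNR average", "LT", 100)))
  expect_equal(lt$subject, "B")
  eq <- filterReport(tab, list(criterion("flip guess", "EQ", "DO_FLIP")))
  expect_equal(eq$subject, "B")
  keep <- filterReport(tab, list(criterion("TSNR average", "LT", 100)),
                       show_keepers = TRUE)
  expect_equal(keep$subject, "A")
  expect_setequal(c(lt$subject, keep$subject), c("A", "B"))

  expect_error(filterReport(tab, list(criterion("nope", "LT", 1))),
               "not in table")
  expect_error(filterReport(tab, list(criterion("flip guess", "GT", 1))),
               "not numeric")
  expect_error(criterion("x", "GT"), "requires")
  expect_error(criterion("x", "VARY", 1), "takes no")
})

test_that("filterReport equals a row-by-row re-evaluation oracle", {
  set.seed(24)
  ops <- c("VARY", "EQ", "GT", "LT", "GE", "LE")
  for (trial in 1:50) {
    n <- sample(2:6, 1)
    dicts <- lapply(seq_len(n), function(i)
      make_dict(m1 = round(runif(1, 0, 10), 2),
                m2 = sample(c("p", "q"), 1),
                m3 = round(runif(2, 0, 5), 2)))   # multi-valued cell
    tab <- buildGroupTable(dicts)
    op <- sample(ops, 1)
    lab <- if (op %in% c("VARY", "EQ")) sample(c("m1", "m2", "m3"), 1)
    else sample(c("m1", "m3"), 1)
    val <- if (op == "VARY") NULL
    else if (lab == "m2") "p" else round(runif(1, 0, 10), 2)
    crit <- criterion(lab, op, val)
    got <- filterReport(tab, list(crit))$subject
    want <- character()
    for (i in seq_len(n)) {
      cell <- entries(dicts[[i]])[[lab]]
      first <- entries(dicts[[1]])[[lab]]
      hit <- switch(op,
        VARY = !identical(cell, first),
        EQ = any(cell == val),
        GT = any(cell > val), LT = any(cell < val),
        GE = any(cell >= val), LE = any(cell <= val))
      if (hit) want <- c(want, tab@subjects[i])
    }
    expect_equal(got, want, info = sprintf("trial %d op %s", trial, op))
    inv <- filterReport(tab, list(crit), show_keepers = TRUE)$subject
    expect_setequal(c(got, inv), tab@subjects)
    expect_length(intersect(got, inv), 0L)
  }
})

test_that("SHOW columns display without triggering", {
  tab <- buildGroupTable(list(make_dict(a = 1, b = 10),
                              make_dict(a = 5, b = 20)), c("s1", "s2"))
  rep <- filterReport(tab, list(criterion("a", "GT", 3),
                                criterion("b", "SHOW")))
  expect_equal(rep$subject, "s2")
  expect_equal(rep$b, "20")
})

test_that("gtkyd scan reports only varying header properties", {
  dir <- withr::local_tempdir()
  spec <- tiny_spec(seed = 61L)
  sim <- simulateEpi(spec)
  p1 <- file.path(dir, "a.nii.gz"); writeVolume(sim$epi, p1)
  p2 <- file.path(dir, "b.nii.gz"); writeVolume(sim$epi, p2)
  p3 <- file.path(dir, "c.nii.gz")
  odd <- dataset4D(values(sim$epi), voxelSize(sim$epi), tr = 2.5,
                   affineMat(sim$epi), runLengths(sim$epi))
  writeVolume(odd, p3)

  res <- gtkydScan(c(p1, p2))
  expect_identical(nrow(res$variability), 0L)

  res3 <- gtkydScan(c(p1, p2, p3))
  expect_true("c.nii.gz" %in% res3$variability$subject)
  expect_equal(res3$variability$tr[res3$variability$subject == "c.nii.gz"],
               "2.5")

  # saturated 12-bit max surfaces through the min/max row
  sat <- sim$epi
  v <- values(sat); v[1, 1, 1, 1] <- 4095; v[v > 4095] <- 4000
  p4 <- file.path(dir, "d.nii.gz")
  writeVolume(dataset4D(v, voxelSize(sat), repTime(sat), affineMat(sat),
                        runLengths(sat)), p4)
  res4 <- gtkydScan(p4)
  expect_equal(res4$table@rows[[1]][["max"]], 4095)

  # unreadable file: error row, scan continues
  p5 <- file.path(dir, "bad.nii")
  writeBin(as.raw(1:32), p5)
  res5 <- suppressWarnings(gtkydScan(c(p1, p5)))
  expect_identical(length(res5$table@subjects), 2L)
  expect_true(!is.null(res5$table@rows[[2]][["error"]]))
})
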