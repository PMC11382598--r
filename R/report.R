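# Static HTML QC report: montage slice selection, alpha thresholding,
# grayplot, edge overlays, block assembly, and the ratings/comments JSON.

.QC_BLOCKS <- c("vorig", "ve2a", "va2t", "vstat", "mot", "mecho", "regr",
                "radcor", "warns", "qsumm")
.RATING_SYMBOLS <- c(good = "+", bad = "X", other = "?")

#' QC block ids in report order
#' @return character vector of the ten block ids.
#' @export
qcBlockIds <- function() .QC_BLOCKS

#' Select montage slice indices within a light automask
#'
#' The automask keeps voxels above 25 percent of the volume's 98th-percentile
#' intensity; slices are evenly spaced within the automask's extent along the
#' chosen axis (an empty automask falls back to the full extent with a
#' warning). A single requested slice lands on the extent midpoint.
#'
#' @param vol a \linkS4class{Dataset3D}.
#' @param axis 1 (sagittal), 2 (coronal) or 3 (axial).
#' @param n_slices number of slices (>= 1).
#' @param auto_frac automask fraction of the 98th percentile (default 0.25).
#' @return list with \code{indices} (1-based) and \code{mm} labels.
#' @export
selectMontageSlices <- function(vol, axis = 3L, n_slices = 5L,
                                auto_frac = 0.25) {
  if (n_slices < 1L) stopf("n_slices must be >= 1")
  v <- vol@values
  thr <- auto_frac * stats::quantile(v, 0.98, type = 7, names = FALSE)
  am <- v > thr
  present <- apply(am, axis, any)
  if (!any(present)) {
    warnf("empty automask; falling back to full axis extent")
    present <- rep(TRUE, dim(v)[axis])
  }
  lo <- min(which(present)); hi <- max(which(present))
  pos <- seq(lo, hi, length.out = n_slices + 2L)[seq_len(n_slices) + 1L]
  idx <- round(pos)
  ctr <- (dim(v) - 1) / 2
  mm <- vapply(idx, function(i) {
    ijk <- ctr; ijk[axis] <- i - 1L
    index_to_mm(vol@affine, ijk)[axis]
  }, numeric(1))
  list(indices = idx, mm = mm)
}

#' Quadratic alpha fade below threshold, with suprathreshold outlines
#'
#' Opacity is 1 at |v| >= thr and \code{(|v|/thr)^2} below; suprathreshold
#' regions get a one-voxel face-boundary outline. The overlay is never
#' restricted to a brain mask.
#'
#' @param overlay 3D numeric array.
#' @param thr positive threshold (scalar).
#' @return list with \code{alpha} (same shape, in [0, 1]), \code{outline}
#'   (logical array), \code{threshold}.
#' @export
applyAlphaThreshold <- function(overlay, thr) {
  if (thr <= 0) stopf("threshold must be positive")
  a <- pmin((abs(overlay) / thr)^2, 1)   # first arg keeps the array dim
  supra <- abs(overlay) >= thr
  dims <- dim(overlay)
  boundary <- array(FALSE, dims)
  if (any(supra)) {
    inner <- supra
    shift <- function(arr, ax, s) {
      out <- array(FALSE, dims)
      n <- dims[ax]
      src <- 1:(n - abs(s)); dst <- src + abs(s)
      if (s < 0) { tmp <- src; src <- dst; dst <- tmp }
      ix <- lapply(dims, seq_len); iy <- ix
      ix[[ax]] <- src; iy[[ax]] <- dst
      out[iy[[1]], iy[[2]], iy[[3]]] <- arr[ix[[1]], ix[[2]], ix[[3]]]
      out
    }
    for (ax in 1:3) for (s in c(-1L, 1L)) inner <- inner & shift(supra, ax, s)
    boundary <- supra & !inner
  }
  list(alpha = a, outline = boundary, threshold = thr)
}

#' Two-sided t threshold for display
#' @param df degrees of freedom.
#' @param p two-sided p value (default 0.001).
#' @return positive t quantile.
#' @export
tStatThreshold <- function(df, p = 0.001) stats::qt(1 - p / 2, df)

#' Percentile-based display range for an F/statistic volume
#'
#' The colorbar maximum is the 99th percentile and the threshold the 90th
#' percentile of in-mask values.
#'
#' @param stat 3D array of statistic values.
#' @param mask a \linkS4class{Mask3D}.
#' @return list with \code{max} and \code{threshold}.
#' @export
percentileRange <- function(stat, mask) {
  v <- stat[mask@values > 0]
  list(max = stats::quantile(v, 0.99, type = 7, names = FALSE),
       threshold = stats::quantile(v, 0.90, type = 7, names = FALSE))
}

#' Grayplot (carpet plot) of in-mask time series
#'
#' Series are Z-scored per voxel and rows ordered by similarity to the
#' leading principal components of the in-mask series (grouped by dominant
#' component, decreasing |correlation| within a group). Grayscale clips
#' at the two-sided p = 0.001 normal quantile (z = 3.2905) so plots compare
#' across subjects. When \code{path} is given a PNG is written with enorm and
#' outlier-fraction traces above the carpet.
#'
#' @param dset a \linkS4class{Dataset4D}.
#' @param mask a nonempty \linkS4class{Mask3D}.
#' @param enorm,outfrac optional per-volume traces drawn above the carpet.
#' @param path optional output PNG path.
#' @return list with \code{matrix} (ordered voxels x time, clipped Z),
#'   \code{ordering} (voxel order within the mask selection), \code{zclip}.
#' @export
renderGrayplot <- function(dset, mask, enorm = NULL, outfrac = NULL,
                           path = NULL) {
  Y <- mask_series(dset, mask)
  sds <- apply(Y, 2L, stats::sd)
  if (all(sds == 0)) stopf("degenerate (constant) dataset")
  Z <- sweep(Y, 2L, colMeans(Y))
  Z[, sds > 0] <- sweep(Z[, sds > 0, drop = FALSE], 2L, sds[sds > 0], "/")
  # similarity ordering: embed every voxel by the angle of its correlations
  # with the two leading principal components, and cut the circle at the
  # widest angular gap — voxels sharing a time course end up contiguous even
  # when the PCs mix two clusters symmetrically
  ev <- eigen(Z %*% t(Z), symmetric = TRUE)
  K <- min(2L, sum(ev$values > 1e-8 * ev$values[1L]))
  r1 <- .corr_with(Z, ev$vectors[, 1L])
  if (K >= 2L) {
    r2 <- .corr_with(Z, ev$vectors[, 2L])
    th <- atan2(r2, r1)
    sth <- sort(th)
    gaps <- diff(c(sth, sth[1L] + 2 * pi))
    cut <- sth[which.max(gaps)] + max(gaps) / 2   # middle of the widest gap
    ordering <- order((th - cut) %% (2 * pi))
  } else ordering <- order(-abs(r1))
  zclip <- stats::qnorm(1 - 0.001 / 2)
  M <- t(Z[, ordering, drop = FALSE])          # voxels x time
  M <- pmin(pmax(M, -zclip), zclip)
  if (!is.null(path)) {
    img <- (M + zclip) / (2 * zclip)
    strip_h <- 24L
    strip <- matrix(1, strip_h, ncol(img))
    draw <- function(strip, series, col_val) {
      if (is.null(series)) return(strip)
      s <- series / max(series, 1e-12)
      for (t in seq_along(s)) {
        row <- strip_h - round(s[t] * (strip_h - 1L))
        strip[max(1L, row), t] <- col_val
      }
      strip
    }
    strip <- draw(strip, enorm, 0)
    strip <- draw(strip, outfrac, 0.5)
    png::writePNG(rbind(strip, img), path)
  }
  list(matrix = M, ordering = ordering, zclip = zclip, path = path)
}

#' Gradient-magnitude edge set of a volume
#'
#' Central-difference gradient magnitude thresholded at the upper quartile of
#' its positive values.
#'
#' @param vol 3D numeric array.
#' @return logical array of edge voxels (empty for a uniform volume).
#' @export
edgeMask <- function(vol) {
  dims <- dim(vol)
  g2 <- array(0, dims)
  for (ax in 1:3) {
    d <- array(0, dims)
    n <- dims[ax]
    if (n >= 3L) {
      hi <- lapply(dims, seq_len); lo <- hi; mid <- hi
      hi[[ax]] <- 3:n; lo[[ax]] <- 1:(n - 2L); mid[[ax]] <- 2:(n - 1L)
      d[mid[[1]], mid[[2]], mid[[3]]] <-
        (vol[hi[[1]], hi[[2]], hi[[3]]] - vol[lo[[1]], lo[[2]], lo[[3]]]) / 2
    }
    g2 <- g2 + d^2
  }
  g <- sqrt(g2)
  pos <- g[g > 0]
  if (!length(pos)) return(array(FALSE, dims))
  g >= stats::quantile(pos, 0.75, type = 7, names = FALSE)
}

.montage_gray <- function(vol, slices, axis = 3L) {
  # normalized grayscale montage matrix from the given slices
  rng <- range(vol)
  norm <- if (diff(rng) > 0) (vol - rng[1]) / diff(rng) else vol * 0
  panes <- lapply(slices, function(s) {
    sl <- switch(axis, norm[s, , ], norm[, s, ], norm[, , s])
    t(sl)[rev(seq_len(ncol(sl))), , drop = FALSE]
  })
  do.call(cbind, panes)
}

#' Render edges of one volume over another
#'
#' Used for the EPI-to-anatomical and anatomical-to-template alignment
#' blocks: gradient edges of \code{edges_src} are drawn in red over a
#' grayscale montage of \code{base}.
#'
#' @param base underlay \linkS4class{Dataset3D}.
#' @param edges_src volume whose edges are drawn (same grid).
#' @param axis,n_slices montage layout.
#' @param path optional output PNG path.
#' @return list with \code{edges} (3D logical), \code{image} (H x W x 3
#'   array), \code{path}.
#' @export
renderEdgeOverlay <- function(base, edges_src, axis = 3L, n_slices = 5L,
                              path = NULL) {
  if (!all(dim(base@values) == dim(edges_src@values))) stopf("grid mismatch")
  edges <- edgeMask(edges_src@values)
  sl <- selectMontageSlices(base, axis, n_slices)$indices
  gray <- .montage_gray(base@values, sl, axis)
  emont <- .montage_gray(edges * 1, sl, axis) > 0.5
  img <- array(rep(gray, 3L), c(dim(gray), 3L))
  img[, , 1][emont] <- 1
  img[, , 2][emont] <- 0
  img[, , 3][emont] <- 0
  if (!is.null(path)) png::writePNG(img, path)
  list(edges = edges, image = img, path = path)
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.review_html <- function(rd) {
  rows <- vapply(names(rd@entries), function(nm)
    sprintf("<tr><td>%s</td><td>%s</td></tr>", .html_escape(nm),
            .html_escape(paste(fmt6(rd@entries[[nm]]), collapse = " "))),
    character(1))
  sprintf("<table class='qsumm'>%s</table>", paste(rows, collapse = "\n"))
}

#' Assemble the QC report directory
#'
#' Writes a self-contained, relocatable directory: \code{index.html} with the
#' ten QC blocks in fixed order (each an anchor usable as a jump target),
#' montage PNGs under \code{media/}, the ratings JSON
#' \code{apqc_<subject>.json}, and the review dict (with ratings merged) as
#' \code{out.ss_review.<subject>.json}. The "warns" menu label is colored by
#' the maximum warning level; the multi-echo block always carries a
#' placeholder note; missing optional inputs skip their images with a log
#' note but never produce a broken link.
#'
#' @param out_dir output directory (created).
#' @param subject subject id.
#' @param epi optional \linkS4class{Dataset4D} (raw EPI; drives vorig, mot).
#' @param anat optional \linkS4class{Dataset3D} (vorig, ve2a).
#' @param template optional \linkS4class{Dataset3D} (va2t).
#' @param mask optional \linkS4class{Mask3D}.
#' @param review optional \linkS4class{ReviewDict} (qsumm block).
#' @param warn_items list of \code{\link{warnItem}}s (warns block).
#' @param stat_maps named list of 3D statistic arrays for vstat (the first is
#'   treated as the omnibus F; at most 1 + 4 maps are rendered).
#' @param corr_maps list of \linkS4class{CorrMap}s (regr / radcor blocks).
#' @param tsnr_table optional data.frame from \code{\link{roiStatsTable}}
#'   with warn columns.
#' @param enorm,outfrac,censor optional motion series for the mot block.
#' @param n_slices montage slice count.
#' @return the report directory path, invisibly.
#' @export
assembleReport <- function(out_dir, subject, epi = NULL, anat = NULL,
                           template = NULL, mask = NULL, review = NULL,
                           warn_items = list(), stat_maps = list(),
                           corr_maps = list(), tsnr_table = NULL,
                           enorm = NULL, outfrac = NULL, censor = NULL,
                           n_slices = 5L) {
  if (is.null(epi) && is.null(anat))
    stopf("at least the original EPI or anatomical input is required")
  dir.create(file.path(out_dir, "media"), recursive = TRUE,
             showWarnings = FALSE)
  media <- character()
  logs <- character()
  add_png <- function(name, writer) {
    p <- file.path(out_dir, "media", name)
    writer(p)
    media <<- c(media, file.path("media", name))
    file.path("media", name)
  }
  body <- list()
  for (blk in .QC_BLOCKS) body[[blk]] <- character()

  vol3 <- function(ds, t = 1L)
    dataset3D(ds@values[, , , t], ds@voxelSize, ds@affine)

  # vorig: example EPI volume + anat with data ranges
  if (!is.null(epi)) {
    rng <- range(epi@values)
    img <- add_png("vorig_epi.png", function(p) {
      v <- vol3(epi)
      sl <- selectMontageSlices(v, 3L, n_slices)$indices
      png::writePNG(.montage_gray(v@values, sl), p)
    })
    body$vorig <- c(body$vorig,
      sprintf("<img src='%s' alt='original EPI'>", img),
      sprintf("<p>EPI value range: [%s, %s]%s</p>", fmt6(rng[1]), fmt6(rng[2]),
              if (rng[2] == 4095) " — maximum 4095: possible 12-bit saturation"
              else ""))
  }
  if (!is.null(anat)) {
    img <- add_png("vorig_anat.png", function(p) {
      sl <- selectMontageSlices(anat, 3L, n_slices)$indices
      png::writePNG(.montage_gray(anat@values, sl), p)
    })
    body$vorig <- c(body$vorig,
                    sprintf("<img src='%s' alt='anatomical'>", img))
  }

  # ve2a / va2t: edge overlays of pre-gridded inputs
  if (!is.null(epi) && !is.null(anat)) {
    img <- add_png("ve2a.png", function(p)
      renderEdgeOverlay(vol3(epi), anat, 3L, n_slices, p))
    body$ve2a <- sprintf("<img src='%s' alt='anat edges on EPI'>", img)
  } else logs <- c(logs, "ve2a: inputs missing, block left empty")
  if (!is.null(anat) && !is.null(template)) {
    img <- add_png("va2t.png", function(p)
      renderEdgeOverlay(template, anat, 3L, n_slices, p))
    body$va2t <- sprintf("<img src='%s' alt='anat edges on template'>", img)
  } else logs <- c(logs, "va2t: no template, block left empty")

  # vstat: omnibus F plus up to four further maps, percentile thresholds
  if (length(stat_maps)) {
    shown <- utils::head(seq_along(stat_maps), 5L)
    for (si in shown) {
      nm <- names(stat_maps)[si]
      stat <- stat_maps[[si]]
      thr <- if (!is.null(mask)) percentileRange(stat, mask)
      else list(max = max(stat), threshold = stats::quantile(stat, 0.9))
      at <- applyAlphaThreshold(stat, max(thr$threshold, 1e-9))
      img <- add_png(sprintf("vstat_%02d.png", si), function(p) {
        base <- if (!is.null(anat)) anat@values else vol3(epi)@values
        sl <- if (!is.null(anat))
          selectMontageSlices(anat, 3L, n_slices)$indices
        else selectMontageSlices(vol3(epi), 3L, n_slices)$indices
        gray <- .montage_gray(base, sl)
        a <- .montage_gray(at$alpha, sl)
        s <- .montage_gray(stat / max(abs(stat)), sl)
        imgarr <- array(rep(gray, 3L), c(dim(gray), 3L))
        imgarr[, , 1] <- pmin(gray * (1 - a) + a * s, 1)
        ol <- .montage_gray(at$outline * 1, sl) > 0.5
        imgarr[, , 1][ol] <- 0; imgarr[, , 2][ol] <- 0
        imgarr[, , 3][ol] <- 0
        png::writePNG(imgarr, p)
      })
      body$vstat <- c(body$vstat,
        sprintf("<h3>%s</h3><img src='%s' alt='%s'>", .html_escape(nm), img,
                .html_escape(nm)),
        sprintf("<p>colorbar max %s (99th percentile in mask), threshold %s (90th percentile), alpha+boxed</p>",
                fmt6(thr$max), fmt6(thr$threshold)))
    }
  } else logs <- c(logs, "vstat: no statistic volumes supplied")

  # mot: grayplot + censor counts
  if (!is.null(epi) && !is.null(mask)) {
    img <- add_png("mot_grayplot.png", function(p)
      renderGrayplot(epi, mask, enorm, outfrac, p))
    body$mot <- sprintf("<img src='%s' alt='grayplot'>", img)
    if (!is.null(censor))
      body$mot <- c(body$mot,
        sprintf("<p>censored %d of %d volumes</p>", sum(censor@keep == 0),
                length(censor@keep)))
  } else logs <- c(logs, "mot: EPI or mask missing")

  body$mecho <- "<p>multi-echo combination not performed for this subject (placeholder)</p>"

  # regr: corr maps labeled regress + ROI TSNR table
  regr_maps <- Filter(function(m) m@kind == "corr_brain", corr_maps)
  for (mi in seq_along(regr_maps)) {
    m <- regr_maps[[mi]]
    img <- add_png(sprintf("regr_corr_%02d.png", mi), function(p) {
      sl_src <- if (!is.null(anat)) anat else
        dataset3D(m@values, voxel_size = c(1, 1, 1))
      sl <- selectMontageSlices(sl_src, 3L, n_slices)$indices
      png::writePNG(.montage_gray(abs(m@values), sl), p)
    })
    body$regr <- c(body$regr,
      sprintf("<img src='%s' alt='corr_brain'>", img),
      sprintf("<p>corr_brain: transparent below |r| = %s, range |r| = %s</p>",
              fmt6(m@thresholds$transparent), fmt6(m@thresholds$range)))
  }
  if (!is.null(tsnr_table)) {
    warn_cols <- grep("^warn_", names(tsnr_table), value = TRUE)
    rows <- vapply(seq_len(nrow(tsnr_table)), function(r) {
      tds <- vapply(names(tsnr_table), function(cn) {
        val <- tsnr_table[r, cn]
        style <- if (cn %in% warn_cols && val != "none")
          sprintf(" style='background:%s'", warnColor(val)) else ""
        sprintf("<td%s>%s</td>", style,
                .html_escape(paste(fmt6(val), collapse = " ")))
      }, character(1))
      sprintf("<tr>%s</tr>", paste(tds, collapse = ""))
    }, character(1))
    body$regr <- c(body$regr, "<h3>ROI TSNR and shape</h3>",
      sprintf("<table class='roi'><tr>%s</tr>%s</table>",
              paste(sprintf("<th>%s</th>", names(tsnr_table)),
                    collapse = ""),
              paste(rows, collapse = "\n")))
  }

  # radcor
  rad_maps <- Filter(function(m) m@kind == "radcor", corr_maps)
  for (mi in seq_along(rad_maps)) {
    m <- rad_maps[[mi]]
    img <- add_png(sprintf("radcor_%02d.png", mi), function(p) {
      sl_src <- if (!is.null(anat)) anat else
        dataset3D(m@values, voxel_size = c(1, 1, 1))
      sl <- selectMontageSlices(sl_src, 3L, n_slices)$indices
      png::writePNG(.montage_gray((m@values + 1) / 2, sl), p)
    })
    body$radcor <- c(body$radcor,
      sprintf("<h3>stage: %s</h3><img src='%s' alt='radcor %s'>",
              .html_escape(m@stage), img, .html_escape(m@stage)))
  }

  # warns
  if (length(warn_items)) {
    body$warns <- vapply(warn_items, function(it)
      sprintf("<p class='warn-%s'><b>%s</b> [%s]: %s</p>",
              as.character(it$level), .html_escape(it$name),
              as.character(it$level), .html_escape(it$message)),
      character(1))
  } else body$warns <- "<p>no warnings</p>"

  # qsumm
  if (!is.null(review)) body$qsumm <- .review_html(review)
  else logs <- c(logs, "qsumm: no review dict supplied")

  max_lv <- as.character(maxWarnLevel(warn_items))
  menu <- vapply(.QC_BLOCKS, function(b) {
    style <- if (b == "warns")
      sprintf(" style='color:%s' data-warn-level='%s'", warnColor(max_lv),
              max_lv) else ""
    sprintf("<a href='#%s'%s>%s</a>", b, style, b)
  }, character(1))

  sections <- vapply(.QC_BLOCKS, function(b)
    sprintf("<section id='%s'>\n<h2>%s</h2>\n%s\n</section>", b, b,
            paste(if (length(body[[b]])) body[[b]]
                  else "<p>(block empty for this run)</p>",
                  collapse = "\n")), character(1))

  html <- c("<!DOCTYPE html>",
            sprintf("<html><head><meta charset='utf-8'><title>QC: %s</title>",
                    .html_escape(subject)),
            "<style>body{font-family:sans-serif;background:#111;color:#eee}",
            "nav{position:sticky;top:0;background:#000;padding:6px}",
            "nav a{margin-right:12px;color:#9f9}",
            "table{border-collapse:collapse} td,th{border:1px solid #555;padding:2px 6px}",
            "</style></head><body>",
            sprintf("<nav>%s</nav>", paste(menu, collapse = " ")),
            sprintf("<h1>Quality control report: %s</h1>",
                    .html_escape(subject)),
            sections,
            "</body></html>")
  writeLines(html, file.path(out_dir, "index.html"))
  if (length(logs)) writeLines(logs, file.path(out_dir, "build_log.txt"))

  # ratings skeleton + review JSON with ratings merged
  ratings <- stats::setNames(
    rep(list(list(rating = "none", comment = "")), length(.QC_BLOCKS) + 1L),
    c(.QC_BLOCKS, "FINAL"))
  jsonlite::write_json(ratings, file.path(out_dir,
                                          sprintf("apqc_%s.json", subject)),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(review)) {
    merged <- review@entries
    merged[["FINAL rating"]] <- "none"
    writeReviewDict(reviewDict(merged),
                    file.path(out_dir,
                              sprintf("out.ss_review.%s.json", subject)),
                    dialect = "json")
  }
  invisible(out_dir)
}

#' Read the ratings JSON of a report
#' @param report_dir report directory.
#' @param subject subject id.
#' @return named list of block ratings/comments.
#' @export
readRatings <- function(report_dir, subject) {
  p <- file.path(report_dir, sprintf("apqc_%s.json", subject))
  if (!file.exists(p)) stopf("no ratings file at %s", p)
  jsonlite::fromJSON(p, simplifyVector = FALSE)
}

#' Apply a rating or comment to a QC block
#'
#' Ratings are "good" (+), "bad" (X), "other" (?) or "none"; symbols are
#' accepted and normalized to words. Saving a comment to an unrated block
#' automatically applies a rating of "other". The FINAL rating is merged into
#' the subject's review JSON, so group filtering can use
#' \code{'FINAL rating' EQ 'bad'}.
#'
#' @param report_dir report directory.
#' @param subject subject id.
#' @param block one of the block ids or "FINAL".
#' @param rating optional rating word or symbol.
#' @param comment optional comment string.
#' @return the updated ratings list, invisibly.
#' @export
rateBlock <- function(report_dir, subject, block, rating = NULL,
                      comment = NULL) {
  ratings <- readRatings(report_dir, subject)
  if (!block %in% names(ratings)) stopf("unknown block id: '%s'", block)
  rec <- ratings[[block]]
  if (!is.null(rating)) {
    if (rating %in% .RATING_SYMBOLS)
      rating <- names(.RATING_SYMBOLS)[match(rating, .RATING_SYMBOLS)]
    rating <- match.arg(rating, c("good", "bad", "other", "none"))
    rec$rating <- rating
  }
  if (!is.null(comment)) {
    rec$comment <- comment
    if (nzchar(comment) && rec$rating == "none") rec$rating <- "other"
  }
  ratings[[block]] <- rec
  jsonlite::write_json(ratings,
                       file.path(report_dir,
                                 sprintf("apqc_%s.json", subject)),
                       auto_unbox = TRUE, pretty = TRUE)
  rev_path <- file.path(report_dir,
                        sprintf("out.ss_review.%s.json", subject))
  if (file.exists(rev_path)) {
    rd <- readReviewDict(rev_path, "json")
    ent <- rd@entries
    ent[["FINAL rating"]] <- ratings$FINAL$rating
    writeReviewDict(reviewDict(ent), rev_path, "json")
  }
  invisible(ratings)
}

#' Rating word/symbol interconversion
#' @param x rating words or symbols.
#' @return the corresponding symbols (for words) or words (for symbols).
#' @export
ratingSymbol <- function(x) {
  ifelse(x %in% names(.RATING_SYMBOLS), unname(.RATING_SYMBOLS[x]),
         ifelse(x %in% .RATING_SYMBOLS,
                names(.RATING_SYMBOLS)[match(x, .RATING_SYMBOLS)], x))
}
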