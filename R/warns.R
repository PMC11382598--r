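# Graded warnings and the artifact detectors of the "warns" report block:
# left-right flip check (local Pearson correlation cost), variance lines,
# pre-steady-state volumes, and the warning-level algebra.

.WARN_LEVELS <- c("none", "undecided", "mild", "medium", "severe")
.WARN_COLORS <- c(none = "green", undecided = "yellow", mild = "#ffc8c8",
                  medium = "#ff8080", severe = "red")

#' Ordered warning level
#'
#' Levels form the total order none < undecided < mild < medium < severe;
#' each carries a display color used by the report.
#'
#' @param level one of "none", "undecided", "mild", "medium", "severe".
#' @return an ordered factor of length 1.
#' @export
warnLevel <- function(level) {
  level <- match.arg(level, .WARN_LEVELS)
  factor(level, levels = .WARN_LEVELS, ordered = TRUE)
}

#' Display color of a warning level
#' @param level a level name or \code{\link{warnLevel}}.
#' @return color string.
#' @export
warnColor <- function(level) unname(.WARN_COLORS[as.character(level)])

#' Construct a warning item
#'
#' @param name unique item name within a report.
#' @param level warning level name.
#' @param message human-readable description.
#' @param payload optional machine-readable details (line coordinates, cost
#'   pair, ...).
#' @return list of class \code{WarnItem}.
#' @export
warnItem <- function(name, level, message, payload = NULL) {
  structure(list(name = name, level = warnLevel(level), message = message,
                 payload = payload), class = "WarnItem")
}

#' Maximum warning level of a set of items
#'
#' @param items list of \code{\link{warnItem}}s (possibly empty).
#' @return a \code{\link{warnLevel}}; "none" for an empty list.
#' @export
maxWarnLevel <- function(items) {
  if (!length(items)) return(warnLevel("none"))
  lv <- vapply(items, function(it) as.character(it$level), character(1))
  warnLevel(.WARN_LEVELS[max(match(lv, .WARN_LEVELS))])
}

#' Serialize warning items to JSON
#' @param items list of \code{\link{warnItem}}s.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeWarnItems <- function(items, path) {
  out <- lapply(items, function(it)
    list(name = it$name, level = as.character(it$level),
         message = it$message, payload = it$payload))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Local Pearson correlation (LPC) alignment cost
#'
#' In-mask voxels are partitioned into non-overlapping cubic blocks of edge
#' \code{2 * block_radius + 1}; per block with at least 8 in-mask voxels the
#' Pearson correlation r of the two intensity sets is computed, and the cost
#' is \code{-sum(w * sign(r) * r^2) / sum(w)} with w the block voxel count.
#' Lower is better; bounded in [-1, 1]. Blocks where either volume is
#' constant are skipped.
#'
#' @param a,b \linkS4class{Dataset3D}s on the same grid.
#' @param mask a nonempty \linkS4class{Mask3D}.
#' @param block_radius half-edge of the cubic blocks in voxels (default 2).
#' @return scalar cost.
#' @export
lpcCost <- function(a, b, mask, block_radius = 2L) {
  if (!all(dim(a@values) == dim(b@values))) stopf("grids differ")
  dims <- dim(a@values)
  edge <- 2L * block_radius + 1L
  msk <- mask@values > 0
  if (!any(msk)) stopf("empty mask")
  num <- 0; den <- 0
  for (k0 in seq(1L, dims[3], by = edge))
    for (j0 in seq(1L, dims[2], by = edge))
      for (i0 in seq(1L, dims[1], by = edge)) {
        ii <- i0:min(i0 + edge - 1L, dims[1])
        jj <- j0:min(j0 + edge - 1L, dims[2])
        kk <- k0:min(k0 + edge - 1L, dims[3])
        sel <- msk[ii, jj, kk]
        w <- sum(sel)
        if (w < 8L) next
        av <- a@values[ii, jj, kk][sel]
        bv <- b@values[ii, jj, kk][sel]
        if (stats::sd(av) == 0 || stats::sd(bv) == 0) next
        r <- stats::cor(av, bv)
        num <- num + w * sign(r) * r^2
        den <- den + w
      }
  if (den == 0) stopf("no valid blocks")
  -num / den
}

#' Left-right flip consistency check
#'
#' Compares the LPC cost of EPI-vs-anatomical "as is" with the cost after
#' mirroring the EPI across its left-right axis (identified from the
#' affine). A relative cost difference above \code{margin} decides DO_FLIP or
#' NO_FLIP; anything closer is UNDECIDED. DO_FLIP raises a severe warning.
#'
#' @param epi_vol a representative EPI \linkS4class{Dataset3D}, already
#'   gridded with the anatomical.
#' @param anat the anatomical \linkS4class{Dataset3D}.
#' @param mask a \linkS4class{Mask3D}.
#' @param block_radius LPC block half-edge.
#' @param margin relative cost margin required for a decision (default 0.02).
#' @return list with \code{cost_asis}, \code{cost_flipped}, \code{guess}
#'   ("NO_FLIP", "DO_FLIP" or "UNDECIDED"), and \code{warn}
#'   (a \code{\link{warnItem}}).
#' @export
checkFlip <- function(epi_vol, anat, mask, block_radius = 2L, margin = 0.02) {
  ax <- lr_axis(epi_vol@affine)
  dims <- dim(epi_vol@values)
  idx <- lapply(dims, seq_len)
  idx[[ax]] <- rev(idx[[ax]])
  flipped <- dataset3D(epi_vol@values[idx[[1]], idx[[2]], idx[[3]]],
                       epi_vol@voxelSize, epi_vol@affine)
  cost_asis <- lpcCost(epi_vol, anat, mask, block_radius)
  cost_flipped <- lpcCost(flipped, anat, mask, block_radius)
  scale <- max(abs(cost_asis), abs(cost_flipped), 1e-6)
  guess <- if (cost_flipped < cost_asis - margin * scale) "DO_FLIP"
  else if (cost_asis < cost_flipped - margin * scale) "NO_FLIP"
  else "UNDECIDED"
  warn <- warnItem("flip check",
                   switch(guess, DO_FLIP = "severe", UNDECIDED = "undecided",
                          NO_FLIP = "none"),
                   sprintf("left-right flip guess: %s (cost as-is %.4f, flipped %.4f)",
                           guess, cost_asis, cost_flipped),
                   payload = list(cost_asis = cost_asis,
                                  cost_flipped = cost_flipped))
  list(cost_asis = cost_asis, cost_flipped = cost_flipped, guess = guess,
       warn = warn)
}

#' Detect through-slice variance lines
#'
#' Voxels are detrended per run (same Legendre order as the outlier counter)
#' and their temporal sd computed. For each in-plane column (i, j) with at
#' least \code{min_frac} of its slices in-mask, the column score is the
#' median sd over in-mask slices; columns scoring above \code{factor} times
#' the median in-mask column score are flagged and face-adjacent flagged
#' columns merge into line clusters. The warning is medium when any line is
#' found and severe for three or more lines (or a score ratio above twice the
#' factor).
#'
#' @param dset a \linkS4class{Dataset4D} (T >= 20).
#' @param mask a nonempty \linkS4class{Mask3D}.
#' @param factor score threshold as a multiple of the median column score
#'   (default 2.5).
#' @param min_frac minimum in-mask slice fraction for a column to be scored
#'   (default 0.5).
#' @return list with \code{lines} (data.frame: i, j of the cluster peak,
#'   score, cluster id, peak mm coordinates) and \code{warn}.
#' @export
findVarianceLines <- function(dset, mask, factor = 2.5, min_frac = 0.5) {
  d <- dim(dset@values)
  if (d[4L] < 20L) stopf("need T >= 20")
  msk <- mask@values > 0
  if (!any(msk)) stopf("empty mask")
  Y <- matrix(dset@values, prod(d[1:3]), d[4L])
  sel <- which(msk)
  R <- detrend_runs(t(Y[sel, , drop = FALSE]), dset@runLengths, dset@tr)
  sdv <- array(NA_real_, d[1:3])
  sdv[sel] <- sqrt(colSums(R^2) / (d[4L] - 1L))
  nslice <- d[3L]
  score <- matrix(NA_real_, d[1L], d[2L])
  for (j in seq_len(d[2L])) for (i in seq_len(d[1L])) {
    col_sd <- sdv[i, j, ]
    n_in <- sum(!is.na(col_sd))
    if (n_in >= min_frac * nslice)
      score[i, j] <- stats::median(col_sd, na.rm = TRUE)
  }
  med <- stats::median(score, na.rm = TRUE)
  flagged <- which(!is.na(score) & score > factor * med, arr.ind = TRUE)
  lines <- data.frame()
  if (nrow(flagged)) {
    # merge face-adjacent flagged columns into clusters
    cl <- integer(nrow(flagged))
    nxt <- 0L
    for (r in seq_len(nrow(flagged))) {
      hit <- which(cl > 0 & abs(flagged[, 1] - flagged[r, 1]) +
                     abs(flagged[, 2] - flagged[r, 2]) == 1L)
      if (length(hit)) cl[r] <- cl[hit[1L]]
      else { nxt <- nxt + 1L; cl[r] <- nxt }
    }
    rows <- lapply(unique(cl), function(cc) {
      mem <- which(cl == cc)
      pk <- mem[which.max(score[flagged[mem, , drop = FALSE]])]
      i <- flagged[pk, 1]; j <- flagged[pk, 2]
      k <- which.max(ifelse(is.na(sdv[i, j, ]), -Inf, sdv[i, j, ]))
      mm <- index_to_mm(dset@affine, c(i, j, k) - 1L)
      data.frame(cluster = cc, i = i, j = j, k = k,
                 score = score[i, j], ratio = score[i, j] / med,
                 x = mm[1], y = mm[2], z = mm[3])
    })
    lines <- do.call(rbind, rows)
  }
  level <- if (!nrow(lines)) "none"
  else if (nrow(lines) >= 3L || max(lines$ratio) > 2 * factor) "severe"
  else "medium"
  warn <- warnItem("variance lines", level,
                   sprintf("%d high-variance line cluster(s) detected",
                           nrow(lines)),
                   payload = if (nrow(lines)) lines else NULL)
  list(lines = lines, warn = warn)
}

#' Count pre-steady-state volumes
#'
#' Counts initial consecutive volumes of each run whose in-mask mean exceeds
#' \code{presteady_factor} times the run's 10 percent trimmed mean of volume
#' means (trimming keeps the artifact from biasing its own baseline). Any
#' nonzero count raises a medium warning; inflation at a non-initial volume
#' is ignored (prefix-only rule).
#'
#' @param dset a \linkS4class{Dataset4D} (T >= 10).
#' @param mask a nonempty \linkS4class{Mask3D}.
#' @param presteady_factor threshold factor (default 1.05).
#' @return list with \code{count} (total over runs), \code{per_run}, and
#'   \code{warn}.
#' @export
checkPresteady <- function(dset, mask, presteady_factor = 1.05) {
  if (dim(dset@values)[4L] < 10L) stopf("need T >= 10")
  Y <- mask_series(dset, mask)
  m <- rowMeans(Y)
  per_run <- integer(length(dset@runLengths))
  start <- 1L
  for (r in seq_along(dset@runLengths)) {
    len <- dset@runLengths[r]
    mr <- m[start:(start + len - 1L)]
    ref <- mean(mr, trim = 0.1)
    n <- 0L
    while (n < len && mr[n + 1L] > presteady_factor * ref) n <- n + 1L
    per_run[r] <- n
    start <- start + len
  }
  count <- sum(per_run)
  warn <- warnItem("pre-steady state", if (count > 0L) "medium" else "none",
                   sprintf("%d apparent pre-steady-state volume(s)", count),
                   payload = list(per_run = per_run))
  list(count = count, per_run = per_run, warn = warn)
}
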