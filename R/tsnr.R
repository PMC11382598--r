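# TSNR maps at processing stages and the per-ROI shape/TSNR table with graded
# warnings.

#' Polynomial-detrended copy of a dataset
#'
#' Residualizes every voxel series against per-run Legendre polynomials
#' (default order \code{1 + floor(run_seconds / 150)}, as used by the outlier
#' and variance-line detectors). Serves as the "noise" input of the
#' volreg-stage TSNR and as a simple errts stand-in on phantoms.
#'
#' @param dset a \linkS4class{Dataset4D}.
#' @param order optional polynomial order override.
#' @return A \linkS4class{Dataset4D} of residuals.
#' @export
detrendDataset <- function(dset, order = NULL) {
  d <- dim(dset@values)
  Y <- t(matrix(dset@values, prod(d[1:3]), d[4L]))
  R <- detrend_runs(Y, dset@runLengths, dset@tr, order)
  dataset4D(array(t(R), d), dset@voxelSize, dset@tr, dset@affine,
            dset@runLengths)
}

#' Temporal signal-to-noise ratio map
#'
#' Per voxel \code{mean(signal) / sd(noise)}. At the "volreg" stage the noise
#' is the detrended series; after regression ("regress") the signal is the
#' full time series and the noise the residuals. Voxels with zero noise sd
#' get value 0.
#'
#' @param signal,noise \linkS4class{Dataset4D}s on the same grid with equal T.
#' @param mask a \linkS4class{Mask3D}; the map is zero outside.
#' @param stage "volreg" or "regress".
#' @return A \linkS4class{TsnrMap}.
#' @export
computeTsnr <- function(signal, noise, mask, stage = c("regress", "volreg")) {
  stage <- match.arg(stage)
  if (!all(dim(signal@values) == dim(noise@values)))
    stopf("signal and noise grids differ")
  S <- mask_series(signal, mask)
  N <- mask_series(noise, mask)
  mu <- colMeans(S)
  sd_n <- sqrt(colMeans(sweep(N, 2L, colMeans(N))^2) *
                 nrow(N) / (nrow(N) - 1L))
  tsnr <- ifelse(sd_n > 0, mu / sd_n, 0)
  vol <- array(0, dim(signal@values)[1:3])
  vol[mask@values > 0] <- tsnr
  new("TsnrMap", values = vol, stage = stage,
      signalSource = if (stage == "regress") "all_runs" else "volreg",
      noiseSource = if (stage == "regress") "errts" else "detrended")
}

#' ROI depth in voxels
#'
#' Face-connected distance transform in which boundary voxels (those with a
#' face neighbor outside the ROI, or at the volume edge) have depth 1.
#' Returns the maximum depth and its location (earliest in index order on
#' ties), in 0-based index and world mm.
#'
#' @param roi a nonempty \linkS4class{Mask3D}.
#' @return list with \code{dvox}, \code{index} (1-based voxel triple) and
#'   \code{mm}.
#' @export
roiDepth <- function(roi) {
  dims <- dim(roi@values)
  inside <- roi@values > 0
  if (!any(inside)) stopf("empty ROI")
  depth <- array(0L, dims)
  cur <- inside
  d <- 0L
  while (any(cur)) {
    d <- d + 1L
    depth[cur] <- d
    # erode: keep voxels whose 6 face neighbors are all present (volume edge
    # counts as absent)
    nxt <- cur
    pad <- function(a, ax, s) {
      # shift logical array by s along axis ax, FALSE-filled
      out <- array(FALSE, dims)
      n <- dims[ax]
      src <- 1:(n - abs(s)); dst <- src + abs(s)
      if (s < 0) { tmp <- src; src <- dst; dst <- tmp }
      idx_src <- lapply(dims, seq_len); idx_src[[ax]] <- src
      idx_dst <- lapply(dims, seq_len); idx_dst[[ax]] <- dst
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
        a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
      out
    }
    for (ax in 1:3) for (s in c(-1L, 1L))
      nxt <- nxt & pad(cur, ax, s)
    cur <- nxt
  }
  amax <- which(depth == d)[1L]
  ijk <- arrayInd(amax, dims)[1L, ]
  list(dvox = d, index = ijk,
       mm = as.numeric(index_to_mm(roi@affine, ijk - 1L)))
}

#' Per-ROI shape and TSNR statistics table
#'
#' One row per nonzero atlas label: voxel count (nvox), count of exactly-zero
#' TSNR voxels (nzer), maximum ROI depth in voxels (dvox) with its mm
#' coordinate, and the min/25\%/median/75\%/max TSNR over all ROI voxels
#' (zeros included; quantile type 7).
#'
#' @param tsnr a \linkS4class{TsnrMap}.
#' @param atlas integer-label \linkS4class{Dataset3D} on the same grid.
#' @param roi_names optional named character vector mapping labels to names.
#' @return data.frame with one row per label.
#' @export
roiStatsTable <- function(tsnr, atlas, roi_names = NULL) {
  if (!all(dim(tsnr@values) == dim(atlas@values))) stopf("grid mismatch")
  labs <- sort(unique(as.integer(atlas@values[atlas@values != 0])))
  if (!length(labs)) stopf("empty atlas")
  rows <- lapply(labs, function(L) {
    sel <- atlas@values == L
    v <- tsnr@values[sel]
    dep <- roiDepth(mask3D(sel, atlas@voxelSize, atlas@affine))
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), type = 7, names = FALSE)
    nm <- if (!is.null(roi_names) && as.character(L) %in% names(roi_names))
      roi_names[[as.character(L)]] else sprintf("toy: ROI %d", L)
    data.frame(label = nm, roi = L, nvox = sum(sel), nzer = sum(v == 0),
               dvox = dep$dvox, tmin = q[1], t25 = q[2], tmed = q[3],
               t75 = q[4], tmax = q[5],
               depth_x = dep$mm[1], depth_y = dep$mm[2], depth_z = dep$mm[3])
  })
  do.call(rbind, rows)
}

#' Default ROI warning thresholds
#'
#' Heuristic cutoffs for the five graded metrics of the ROI table; each entry
#' lists the boundary for mild/medium/severe in the direction the metric
#' degrades. All values are overridable.
#'
#' @return nested list of thresholds.
#' @export
roiWarnThresholds <- function() {
  list(nvox = list(mild = 20, medium = 10, severe = 5),        # small is bad
       zero_frac = list(mild = 0.1, medium = 0.25, severe = 0.5),
       dvox = list(mild = 3, medium = 2, severe = NA),          # small is bad
       t75 = list(mild = 50, medium = 30, severe = 15),         # small is bad
       slope = list(mild = 0.75, medium = 1.0, severe = 1.5))   # big is bad
}

.grade_low <- function(x, th) {
  if (!is.na(th$severe) && x < th$severe) "severe"
  else if (x < th$medium) "medium"
  else if (x < th$mild) "mild"
  else "none"
}
.grade_high <- function(x, th) {
  if (!is.na(th$severe) && x > th$severe) "severe"
  else if (x > th$medium) "medium"
  else if (x > th$mild) "mild"
  else "none"
}

#' Grade one ROI-table row
#'
#' Metrics: small nvox, high nzer/nvox, small dvox, low t75, and high TSNR
#' quartile slope (t75 - t25)/tmed. A zero median makes the slope severe
#' rather than dividing by zero. Levels are monotone nondecreasing as each
#' metric degrades.
#'
#' @param row one row of \code{\link{roiStatsTable}} output.
#' @param thresholds configuration as from \code{\link{roiWarnThresholds}}.
#' @return the row with warn columns \code{warn_nvox}, \code{warn_zero},
#'   \code{warn_dvox}, \code{warn_t75}, \code{warn_slope} and the overall
#'   \code{warn_max} appended.
#' @export
assignRoiWarnLevels <- function(row, thresholds = roiWarnThresholds()) {
  w <- list(
    warn_nvox = .grade_low(row$nvox, thresholds$nvox),
    warn_zero = .grade_high(row$nzer / row$nvox, thresholds$zero_frac),
    warn_dvox = .grade_low(row$dvox, thresholds$dvox),
    warn_t75 = .grade_low(row$t75, thresholds$t75),
    warn_slope = if (row$tmed == 0) "severe"
                 else .grade_high((row$t75 - row$t25) / row$tmed,
                                  thresholds$slope))
  row[names(w)] <- unlist(w)
  row$warn_max <- as.character(maxWarnLevel(
    lapply(unlist(w), function(l) warnItem("roi", l, ""))))
  row
}
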