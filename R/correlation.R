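# Global correlation (GCOR), corr_brain, radial correlation, seed-based
# correlation, and mask Dice.

.unit_series <- function(Y) {
  Yc <- sweep(Y, 2L, colMeans(Y))
  nrm <- sqrt(colSums(Yc^2))
  keep <- nrm > 0
  list(U = sweep(Yc[, keep, drop = FALSE], 2L, nrm[keep], "/"), keep = keep)
}

#' Global correlation (GCOR)
#'
#' Each in-mask series is demeaned and scaled to unit norm; GCOR is the
#' squared norm of the mean of these unit series, which equals the average of
#' all pairwise correlations (self-pairs included). Zero-variance voxels are
#' excluded with a message.
#'
#' @param dset a \linkS4class{Dataset4D} (T >= 3).
#' @param mask a \linkS4class{Mask3D} with at least two nonzero-variance
#'   voxels.
#' @return scalar GCOR.
#' @export
computeGcor <- function(dset, mask) {
  if (dim(dset@values)[4L] < 3L) stopf("need T >= 3")
  Y <- mask_series(dset, mask)
  u <- .unit_series(Y)
  if (sum(!u$keep)) message(sprintf("GCOR: excluded %d zero-variance voxels",
                                    sum(!u$keep)))
  if (ncol(u$U) < 2L) stopf("need at least 2 in-mask voxels with variance")
  g <- rowMeans(u$U)
  sum(g^2)
}

.corr_with <- function(Y, ref) {
  # Pearson correlation of each column of Y with the reference series;
  # zero-variance columns (or reference) give 0.
  Yc <- sweep(Y, 2L, colMeans(Y))
  rc <- ref - mean(ref)
  denom <- sqrt(colSums(Yc^2)) * sqrt(sum(rc^2))
  r <- as.numeric(crossprod(Yc, rc))
  ifelse(denom > 0, r / denom, 0)
}

#' Correlation of each voxel with the mean in-mask residual (corr_brain)
#'
#' Render metadata carries the default display rule for this map: transparent
#' below |r| = 0.3, colorbar range |r| = 0.6.
#'
#' @param errts residual \linkS4class{Dataset4D}.
#' @param mask a \linkS4class{Mask3D}.
#' @param stage processing-stage label.
#' @return A \linkS4class{CorrMap} of kind "corr_brain".
#' @export
computeCorrBrain <- function(errts, mask, stage = "regress") {
  Y <- mask_series(errts, mask)
  gm <- rowMeans(Y)
  r <- .corr_with(Y, gm)
  vol <- array(0, dim(errts@values)[1:3])
  vol[mask@values > 0] <- r
  new("CorrMap", values = vol, kind = "corr_brain", seed = numeric(),
      stage = stage, thresholds = list(transparent = 0.3, range = 0.6))
}

#' Radial correlation map (radcor)
#'
#' Per voxel, the Pearson correlation between its series and the
#' Gaussian-weighted average series of its neighborhood (default FWHM 20 mm),
#' computed by smoothing each volume within the mask and renormalizing by the
#' smoothed mask weight. The center voxel is included in its own average.
#'
#' @param dset a \linkS4class{Dataset4D}.
#' @param mask a \linkS4class{Mask3D}.
#' @param fwhm Gaussian full width at half maximum in mm (default 20).
#' @param stage processing-stage label ("tcat", "volreg" or "regress").
#' @return A \linkS4class{CorrMap} of kind "radcor".
#' @export
computeRadcor <- function(dset, mask, fwhm = 20, stage = "tcat") {
  if (fwhm <= 0) stopf("fwhm must be > 0")
  if (fwhm < min(dset@voxelSize))
    warnf("fwhm %g mm is below one voxel; radcor degenerates to self-correlation",
          fwhm)
  d <- dim(dset@values)
  sigma_vox <- (fwhm / 2.3548200450309493) / dset@voxelSize
  m <- mask@values * 1
  wden <- smooth3d(m, sigma_vox)
  sel <- which(m > 0)
  T <- d[4L]
  nb <- matrix(0, T, length(sel))   # neighborhood-average series per voxel
  for (t in seq_len(T)) {
    sm <- smooth3d(dset@values[, , , t] * m, sigma_vox)
    nb[t, ] <- sm[sel] / wden[sel]
  }
  Y <- mask_series(dset, mask)
  Yc <- sweep(Y, 2L, colMeans(Y)); Nc <- sweep(nb, 2L, colMeans(nb))
  denom <- sqrt(colSums(Yc^2) * colSums(Nc^2))
  r <- ifelse(denom > 0, colSums(Yc * Nc) / denom, 0)
  vol <- array(0, d[1:3])
  vol[sel] <- pmin(1, pmax(-1, r))
  new("CorrMap", values = vol, kind = "radcor", seed = numeric(),
      stage = stage, thresholds = list(transparent = 0.3, range = 0.6))
}

#' Seed-based correlation map
#'
#' Correlates every in-mask voxel with the series at the seed coordinate
#' (mm). A seed outside the mask snaps to the nearest in-mask voxel with a
#' warning.
#'
#' @param dset a \linkS4class{Dataset4D}.
#' @param mask a \linkS4class{Mask3D}.
#' @param seed_mm world coordinate (length 3, mm).
#' @param stage processing-stage label.
#' @return A \linkS4class{CorrMap} of kind "seed" (value 1 at the seed).
#' @export
computeSeedCorr <- function(dset, mask, seed_mm, stage = "regress") {
  d <- dim(dset@values)
  ijk <- mm_to_index(dset@affine, seed_mm) + 1L   # to 1-based
  sel <- which(mask@values > 0)
  coords <- arrayInd(sel, d[1:3])
  inside <- all(ijk >= 1L & ijk <= d[1:3]) &&
    mask@values[ijk[1], ijk[2], ijk[3]] > 0
  if (!inside) {
    d2 <- colSums((t(coords) - as.numeric(ijk))^2)
    ijk <- coords[which.min(d2), ]
    warnf("seed outside mask; snapped to nearest in-mask voxel (%d, %d, %d)",
          ijk[1], ijk[2], ijk[3])
  }
  ref <- dset@values[ijk[1], ijk[2], ijk[3], ]
  Y <- mask_series(dset, mask)
  r <- .corr_with(Y, ref)
  vol <- array(0, d[1:3])
  vol[sel] <- pmin(1, pmax(-1, r))
  new("CorrMap", values = vol, kind = "seed",
      seed = as.numeric(index_to_mm(dset@affine, ijk - 1L)), stage = stage,
      thresholds = list(transparent = 0.3, range = 0.6))
}

#' Toy resting-state seed table for the phantom
#'
#' Mimics the three default networks of template-based seed maps (default
#' mode with a posterior-cingulate-like left seed, visual right, auditory
#' left), expressed in the phantom's world coordinates.
#'
#' @param mask a \linkS4class{Mask3D} giving the grid and affine.
#' @return data.frame with columns network, x, y, z (mm).
#' @export
toySeedTable <- function(mask) {
  d <- dim(mask@values)
  ctr <- (d - 1) / 2
  off <- round(d / 5)
  seeds <- rbind(
    DMN      = c(ctr[1] - off[1], ctr[2] - off[2], ctr[3]),
    visual   = c(ctr[1] + off[1], ctr[2] - off[2], ctr[3]),
    auditory = c(ctr[1] - off[1], ctr[2] + off[2], ctr[3]))
  mm <- index_to_mm(mask@affine, seeds)
  data.frame(network = rownames(seeds), x = mm[, 1], y = mm[, 2], z = mm[, 3],
             row.names = NULL)
}

#' Dice coefficient of two masks
#'
#' @param a,b \linkS4class{Mask3D} objects on the same grid.
#' @return \code{2|A \& B| / (|A| + |B|)}; both-empty input is an error.
#' @export
diceCoefficient <- function(a, b) {
  if (!all(dim(a@values) == dim(b@values))) stopf("mask grids differ")
  na <- sum(a@values > 0); nb <- sum(b@values > 0)
  if (na + nb == 0) stopf("both masks are empty")
  2 * sum(a@values > 0 & b@values > 0) / (na + nb)
}
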