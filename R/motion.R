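# Motion Euclidean norm, voxelwise outlier fractions, min-outlier volume
# selection, censor construction, and before/after-censoring summaries.

#' Euclidean norm of forward motion differences (enorm)
#'
#' \code{e[t] = sqrt(sum_k (p_k[t] - p_k[t-1])^2)} within each run, with
#' \code{e = 0} at the first volume of every run. Rotations (degrees) and
#' translations (mm) enter unscaled, following the usual convention for this
#' statistic; the mixing of units is a documented caveat.
#'
#' @param mp a \linkS4class{Matrix1D} of T x 6 motion parameters.
#' @param run_lengths per-run volume counts (default: one run).
#' @return numeric length-T series.
#' @export
computeEnorm <- function(mp, run_lengths = nrow(mp@values)) {
  m <- mp@values
  if (ncol(m) != 6L) stopf("motion parameters must have 6 columns, got %d",
                           ncol(m))
  if (sum(run_lengths) != nrow(m)) stopf("run lengths do not sum to T")
  e <- numeric(nrow(m))
  start <- 1L
  for (len in run_lengths) {
    idx <- start:(start + len - 1L)
    if (len > 1L) {
      d <- diff(m[idx, , drop = FALSE])
      e[idx[-1L]] <- sqrt(rowSums(d^2))
    }
    start <- start + len
  }
  e
}

#' Per-volume fraction of in-mask outlier voxels
#'
#' Each in-mask voxel is detrended per run with Legendre polynomials of order
#' \code{1 + floor(run_seconds / 150)}; a residual is an outlier when its
#' magnitude exceeds \code{qnorm(1 - 0.001/(2 T)) * 1.4826 * MAD} of that
#' voxel's run residuals (T the run length). The returned series is the
#' in-mask outlier fraction per volume, in [0, 1].
#'
#' @param dset a \linkS4class{Dataset4D} (T >= 10).
#' @param mask a nonempty \linkS4class{Mask3D} on the same grid.
#' @return numeric length-T series.
#' @export
computeOutlierFraction <- function(dset, mask) {
  if (sum(mask@values) == 0) stopf("empty mask")
  T <- dim(dset@values)[4L]
  if (T < 10L) stopf("need at least 10 volumes")
  Y <- mask_series(dset, mask)           # T x N
  out <- matrix(FALSE, T, ncol(Y))
  start <- 1L
  for (len in dset@runLengths) {
    idx <- start:(start + len - 1L)
    R <- detrend_runs(Y[idx, , drop = FALSE], len, dset@tr)
    mad_n <- 1.4826 * apply(abs(R), 2L, stats::median)
    thr <- stats::qnorm(1 - 0.001 / (2 * len)) * mad_n
    out[idx, ] <- sweep(abs(R), 2L, thr, ">")
    start <- start + len
  }
  rowMeans(out)
}

#' Index of the minimum-outlier volume
#'
#' Ties resolve to the earliest volume. \code{censorable_prefix} initial
#' volumes can be excluded from the search (e.g. a pre-steady-state guard).
#'
#' @param outfrac outlier-fraction series.
#' @param censorable_prefix number of initial volumes to skip (default 0).
#' @return 1-based volume index.
#' @export
selectMinOutlierVolume <- function(outfrac, censorable_prefix = 0L) {
  if (!length(outfrac)) stopf("empty series")
  off <- min(censorable_prefix, length(outfrac) - 1L)
  off + which.min(outfrac[(off + 1L):length(outfrac)])
}

#' Build the censor vector from enorm and outlier series
#'
#' Volume t is censored when \code{enorm[t] > enorm_limit} (and, when
#' \code{extend_previous}, volume t-1 of the same run as well — a forward
#' difference implicates both members of the pair) or when
#' \code{outfrac[t] > outlier_limit}.
#'
#' @param enorm,outfrac equal-length series.
#' @param enorm_limit,outlier_limit positive censor limits (defaults 0.3 mm
#'   and 0.05).
#' @param extend_previous censor the volume before each suprathreshold enorm
#'   (default TRUE).
#' @param run_lengths per-run volume counts.
#' @return A \linkS4class{CensorVector}.
#' @export
buildCensor <- function(enorm, outfrac, enorm_limit = 0.3,
                        outlier_limit = 0.05, extend_previous = TRUE,
                        run_lengths = length(enorm)) {
  if (length(enorm) != length(outfrac)) stopf("series lengths differ")
  if (enorm_limit <= 0 || outlier_limit <= 0) stopf("limits must be positive")
  T <- length(enorm)
  cens <- enorm > enorm_limit | outfrac > outlier_limit
  if (extend_previous) {
    start <- 1L
    for (len in run_lengths) {
      idx <- start:(start + len - 1L)
      over <- idx[enorm[idx] > enorm_limit]
      prev <- over[over > start] - 1L
      cens[prev] <- TRUE
      start <- start + len
    }
  }
  censorVector(as.numeric(!cens), enorm_limit, outlier_limit)
}

#' Censor summary as review-dict entries
#'
#' @param cv a \linkS4class{CensorVector}.
#' @param run_lengths per-run volume counts.
#' @return named list of review entries (total/censored/applied TR counts,
#'   censor fraction at 6 significant digits, per-run fractions).
#' @export
censorSummary <- function(cv, run_lengths = length(cv@keep)) {
  T <- length(cv@keep)
  if (sum(run_lengths) != T) stopf("run lengths do not sum to T")
  ncens <- sum(cv@keep == 0)
  per_run <- integer(length(run_lengths))
  per_app <- integer(length(run_lengths))
  frac_run <- numeric(length(run_lengths))
  start <- 1L
  for (r in seq_along(run_lengths)) {
    idx <- start:(start + run_lengths[r] - 1L)
    per_run[r] <- run_lengths[r]
    per_app[r] <- sum(cv@keep[idx] == 1)
    frac_run[r] <- signif(sum(cv@keep[idx] == 0) / run_lengths[r], 6)
    start <- start + run_lengths[r]
  }
  list(
    "num runs found" = length(run_lengths),
    "num TRs per run" = per_run,
    "num TRs per run (applied)" = per_app,
    "num TRs per run (censored)" = per_run - per_app,
    "fraction censored per run" = frac_run,
    "TRs total (uncensored)" = T,
    "TRs total" = T - ncens,
    "TRs censored" = ncens,
    "censor fraction" = round(ncens / T, 6))
}

#' Before/after-censoring distribution statistics
#'
#' Quartiles use linear interpolation (quantile type 7). The AC (after
#' censoring) set covers kept volumes only; when everything is censored the AC
#' entries are NA and \code{ac_defined} is FALSE.
#'
#' @param series numeric series.
#' @param cv a \linkS4class{CensorVector} of the same length.
#' @return list with \code{bc}, \code{ac} (each min/q25/median/q75/max) and
#'   \code{ac_defined}.
#' @export
distributionStats <- function(series, cv) {
  if (!length(series)) stopf("empty series")
  five <- function(x) {
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
    list(min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5])
  }
  kept <- series[cv@keep == 1]
  list(bc = five(series),
       ac = if (length(kept)) five(kept)
            else list(min = NA_real_, q25 = NA_real_, median = NA_real_,
                      q75 = NA_real_, max = NA_real_),
       ac_defined = length(kept) > 0L)
}
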