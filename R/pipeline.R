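# Single-subject QC pipeline: runs every metric module on already-gridded
# inputs and assembles the review dict plus the HTML report.

#' Run the full single-subject QC pipeline
#'
#' Computes motion censoring, outlier fractions, GCOR, corr_brain, radial
#' correlation, volreg-stage TSNR with the per-ROI table, ideal stimulus
#' responses and DF accounting (when timing is given), the flip /
#' variance-line / pre-steady-state checks, merges everything into a review
#' dictionary, and (optionally) writes the HTML report directory.
#'
#' @param epi a \linkS4class{Dataset4D}.
#' @param anat optional \linkS4class{Dataset3D} on the EPI grid.
#' @param mask a \linkS4class{Mask3D}.
#' @param motion a \linkS4class{Matrix1D} of T x 6 motion parameters.
#' @param atlas optional label \linkS4class{Dataset3D} for the ROI table.
#' @param stim_onsets,stim_durations optional stimulus timing (seconds).
#' @param hrf response kernel for the ideal responses.
#' @param enorm_limit,outlier_limit censor limits.
#' @param n_drift drift regressor count per run for DF accounting.
#' @param out_dir optional report directory; when NULL no report is written.
#' @param subject subject id used in report file names.
#' @return list with review (\linkS4class{ReviewDict}), censor, enorm,
#'   outfrac, tsnr, tsnr_table, corr_maps, warn_items, flip, report_dir.
#' @export
runSubjectQc <- function(epi, anat = NULL, mask, motion, atlas = NULL,
                         stim_onsets = list(), stim_durations = list(),
                         hrf = "gamma", enorm_limit = 0.3,
                         outlier_limit = 0.05, n_drift = 3L,
                         out_dir = NULL, subject = "subj") {
  T <- dim(epi@values)[4L]
  rl <- epi@runLengths
  en <- computeEnorm(motion, rl)
  of <- computeOutlierFraction(epi, mask)
  cv <- buildCensor(en, of, enorm_limit, outlier_limit, run_lengths = rl)
  cs <- censorSummary(cv, rl)

  errts <- detrendDataset(epi)
  g <- computeGcor(epi, mask)
  cb <- computeCorrBrain(errts, mask)
  rc <- computeRadcor(epi, mask, stage = "tcat")
  tsnr <- computeTsnr(epi, errts, mask, "volreg")
  tsnr_avg <- mean(tsnr@values[mask@values > 0])
  tsnr_table <- NULL
  if (!is.null(atlas)) {
    tab <- roiStatsTable(tsnr, atlas)
    tsnr_table <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
      assignRoiWarnLevels(tab[i, ])))
  }

  warn_items <- list()
  flip <- NULL
  if (!is.null(anat)) {
    epi_vol <- dataset3D(epi@values[, , , 1L], epi@voxelSize, epi@affine)
    flip <- checkFlip(epi_vol, anat, mask)
    warn_items <- c(warn_items, list(flip$warn))
  }
  vl <- findVarianceLines(epi, mask)
  ps <- checkPresteady(epi, mask)
  warn_items <- c(warn_items, list(vl$warn, ps$warn))

  stim_frag <- list()
  ideal <- NULL
  n_stim <- length(stim_onsets)
  if (n_stim) {
    ideal <- buildIdealResponse(stim_onsets, stim_durations, hrf,
                                tr = epi@tr, n_volumes = T)
    scf <- stimCensorFractions(ideal, cv)
    warn_items <- c(warn_items, scf$warns)
    design <- matrix1D(ideal$series, ideal$labels)
    warn_items <- c(warn_items, cormatWarnings(design))
    stim_frag <- list(
      "num regs of interest" = n_stim,
      "num TRs per stim (orig)" = scf$n_response,
      "num TRs censored per stim" = scf$n_censored,
      "fraction TRs censored" = scf$fraction)
  }
  df <- dfAccounting(T, sum(cv@keep == 0), n_motion = 6L,
                     n_drift = n_drift * length(rl), n_stim = n_stim)
  if (!is.null(df$warn)) warn_items <- c(warn_items, list(df$warn))

  review <- buildSsReview(
    cs, stim_frag,
    list("degrees of freedom used" = df$used_by_regressors,
         "degrees of freedom left" = df$left,
         "final DF fraction" = signif(df$final_fraction, 6),
         "TSNR average" = signif(tsnr_avg, 6),
         "global correlation (GCOR)" = signif(g, 6)),
    if (!is.null(flip)) list("flip guess" = flip$guess) else list())

  report_dir <- NULL
  if (!is.null(out_dir)) {
    fmap <- array(0, dim(epi@values)[1:3])
    fmap[mask@values > 0] <-
      (tsnr@values[mask@values > 0] / max(tsnr@values))^2 * 50
    assembleReport(out_dir, subject, epi = epi, anat = anat, mask = mask,
                   review = review, warn_items = warn_items,
                   stat_maps = list("Full F" = fmap),
                   corr_maps = list(cb, rc), tsnr_table = tsnr_table,
                   enorm = en, outfrac = of, censor = cv)
    report_dir <- out_dir
  }
  list(review = review, censor = cv, enorm = en, outfrac = of, tsnr = tsnr,
       tsnr_table = tsnr_table, corr_maps = list(corr_brain = cb,
                                                 radcor = rc),
       warn_items = warn_items, flip = flip, ideal = ideal,
       df = df, report_dir = report_dir)
}
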