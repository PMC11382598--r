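# Ideal stimulus responses, degree-of-freedom accounting (including bandpass
# cost), per-stimulus censor fractions, and design-matrix collinearity
# warnings.

.hrf_kernel <- function(hrf, dt, span = 30) {
  t <- seq(0, span, by = dt)
  switch(hrf,
    gamma = {
      p <- 4.5; q <- 4
      h <- (t / p)^q * exp(q - q * t / p)   # unit peak at t = p
      h
    },
    identity = c(1, rep(0, length(t) - 1L)),
    block = c(1, rep(0, length(t) - 1L)))   # block = boxcar itself
}

#' Idealized stimulus responses
#'
#' Each stimulus is a boxcar of its onsets/durations convolved with a
#' unit-peak response kernel ("gamma": a gamma-variate peaking at 4.5 s;
#' "block": the boxcar itself; "identity": a delta, useful for checks),
#' sampled at the TR grid. The summed series is the elementwise sum over
#' stimuli.
#'
#' @param onsets list with one numeric vector of onset seconds per stimulus.
#' @param durations list of per-stimulus durations in seconds (scalar each,
#'   or one per onset).
#' @param hrf kernel choice.
#' @param tr sampling interval in seconds.
#' @param n_volumes length of the sampled series.
#' @param labels optional stimulus labels.
#' @return list of class \code{IdealResponse} with \code{series} (T x
#'   n_stim matrix), \code{sum} (length-T), \code{labels}.
#' @export
buildIdealResponse <- function(onsets, durations, hrf = c("gamma", "block",
                                                          "identity"),
                               tr = 2, n_volumes = 200L, labels = NULL) {
  hrf <- match.arg(hrf)
  dt <- tr / 20
  run_end <- n_volumes * tr
  n_fine <- ceiling(run_end / dt) + 1L
  kern <- .hrf_kernel(hrf, dt)
  S <- matrix(0, n_volumes, length(onsets))
  for (s in seq_along(onsets)) {
    ons <- onsets[[s]]
    if (any(ons > run_end)) stopf("stimulus %d: onset beyond run end", s)
    dur <- durations[[s]]
    if (length(dur) == 1L) dur <- rep(dur, length(ons))
    box <- numeric(n_fine)
    for (e in seq_along(ons)) {
      i0 <- floor(ons[e] / dt) + 1L
      i1 <- min(n_fine, i0 + max(0L, ceiling(dur[e] / dt) - 1L))
      box[i0:i1] <- 1
    }
    conv <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_fine)]
    if (max(abs(conv)) > 0) conv <- conv / max(conv)   # unit peak response
    S[, s] <- conv[round((0:(n_volumes - 1L)) * tr / dt) + 1L]
  }
  if (is.null(labels)) labels <- sprintf("stim%02d", seq_along(onsets))
  structure(list(series = S, sum = rowSums(S), labels = labels, hrf = hrf,
                 tr = tr), class = "IdealResponse")
}

#' Regressors consumed by a frequency bandpass
#'
#' For DFT frequencies \code{f_k = k / (T * tr)}, k = 1..floor(T/2), each
#' frequency outside the retained band [fbot, ftop] (endpoints inclusive)
#' costs 2 degrees of freedom (sine and cosine), except the Nyquist bin for
#' even T which costs 1. DC is excluded (drift regressors own it).
#'
#' @param T number of volumes.
#' @param tr repetition time, seconds.
#' @param band length-2 retained band in Hz, within (0, Nyquist].
#' @return integer regressor count.
#' @export
countBandpassRegressors <- function(T, tr, band = c(0.01, 0.1)) {
  nyq <- 1 / (2 * tr)
  if (band[1] < 0 || band[2] <= band[1] || band[2] > nyq + 1e-12)
    stopf("band must satisfy 0 <= fbot < ftop <= Nyquist (%g Hz)", nyq)
  k <- seq_len(floor(T / 2))
  f <- k / (T * tr)
  out <- f < band[1] | f > band[2]
  cost <- ifelse(T %% 2 == 0 & k == T / 2, 1L, 2L)
  sum(cost[out])
}

#' Degree-of-freedom accounting
#'
#' \code{left = T - n_censored - (motion + drift + stim + bandpass)} and
#' \code{final_fraction = left / T}. A negative remainder is clamped to zero
#' and flagged severe.
#'
#' @param T total volumes.
#' @param n_censored censored volumes.
#' @param n_motion,n_drift,n_stim,n_bandpass regressor counts.
#' @return list of class \code{DFSummary}: total, censored,
#'   used_by_regressors, left, final_fraction, warn.
#' @export
dfAccounting <- function(T, n_censored = 0L, n_motion = 0L, n_drift = 0L,
                         n_stim = 0L, n_bandpass = 0L) {
  cnt <- c(T, n_censored, n_motion, n_drift, n_stim, n_bandpass)
  if (any(cnt < 0)) stopf("counts must be nonnegative")
  used <- n_motion + n_drift + n_stim + n_bandpass
  left <- T - n_censored - used
  warn <- NULL
  if (left < 0) {
    warn <- warnItem("degrees of freedom", "severe",
                     sprintf("model consumes %d more DFs than available",
                             -left))
    left <- 0L
  }
  structure(list(total = T, censored = n_censored, used_by_regressors = used,
                 left = left, final_fraction = left / T, warn = warn),
            class = "DFSummary")
}

#' Per-stimulus censored response fractions
#'
#' For each stimulus, the fraction of volumes with a nonzero idealized
#' response that were censored, rounded to 3 decimals for reporting. A
#' stimulus with no response volumes yields NA with a flag; a fully censored
#' stimulus raises a severe warning.
#'
#' @param ideal an \code{IdealResponse}.
#' @param cv a \linkS4class{CensorVector} of matching length.
#' @return list with \code{fraction} (rounded), \code{n_response},
#'   \code{n_censored}, and \code{warns}.
#' @export
stimCensorFractions <- function(ideal, cv) {
  if (nrow(ideal$series) != length(cv@keep)) stopf("lengths differ")
  ns <- ncol(ideal$series)
  n_resp <- integer(ns); n_cens <- integer(ns); frac <- numeric(ns)
  warns <- list()
  for (s in seq_len(ns)) {
    resp <- which(abs(ideal$series[, s]) > 1e-8)
    n_resp[s] <- length(resp)
    if (!length(resp)) {
      frac[s] <- NA_real_
      warns[[length(warns) + 1L]] <-
        warnItem(sprintf("stim %s response", ideal$labels[s]), "undecided",
                 "stimulus has no response volumes; fraction undefined")
      next
    }
    n_cens[s] <- sum(cv@keep[resp] == 0)
    frac[s] <- round(n_cens[s] / n_resp[s], 3)
    if (frac[s] == 1)
      warns[[length(warns) + 1L]] <-
        warnItem(sprintf("stim %s censoring", ideal$labels[s]), "severe",
                 "all response volumes of this stimulus are censored")
  }
  list(fraction = frac, n_response = n_resp, n_censored = n_cens,
       warns = warns)
}

#' Design-matrix collinearity warnings
#'
#' Lists all column pairs whose |Pearson r| reaches the warning thresholds
#' (defaults: 0.4 mild, 0.6 medium, 0.9 severe; identical columns are
#' severe). Constant columns are flagged separately and excluded from
#' pairwise checks.
#'
#' @param design a \linkS4class{Matrix1D} with at least 2 columns.
#' @param thresholds named list of |r| cutoffs.
#' @return list of \code{\link{warnItem}}s (possibly empty).
#' @export
cormatWarnings <- function(design, thresholds = list(mild = 0.4,
                                                     medium = 0.6,
                                                     severe = 0.9)) {
  X <- design@values
  if (ncol(X) < 2L) stopf("need at least 2 design columns")
  labs <- if (length(design@columnLabels)) design@columnLabels
  else sprintf("col%d", seq_len(ncol(X)))
  items <- list()
  sds <- apply(X, 2L, stats::sd)
  for (c0 in which(sds == 0))
    items[[length(items) + 1L]] <-
      warnItem(sprintf("constant column %s", labs[c0]), "medium",
               sprintf("design column '%s' is constant", labs[c0]))
  ok <- which(sds > 0)
  if (length(ok) >= 2L) {
    for (a in seq_along(ok)[-length(ok)]) for (b in (a + 1L):length(ok)) {
      i <- ok[a]; j <- ok[b]
      r <- stats::cor(X[, i], X[, j])
      lev <- if (abs(r) >= thresholds$severe) "severe"
      else if (abs(r) >= thresholds$medium) "medium"
      else if (abs(r) >= thresholds$mild) "mild"
      else next
      items[[length(items) + 1L]] <-
        warnItem(sprintf("correlated pair %s ~ %s", labs[i], labs[j]), lev,
                 sprintf("design columns '%s' and '%s' have |r| = %.3f",
                         labs[i], labs[j], abs(r)),
                 payload = list(i = i, j = j, r = r))
    }
  }
  items
}
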