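# Synthetic phantom generation: anatomical/EPI volumes, toy atlases, motion
# traces and stimulus timings, with a machine-readable ground-truth record so
# every detector in the package can be tested without external data.

#' Simulation specification
#'
#' Collects every knob of the synthetic subject. The defaults describe the
#' standard test phantom: a 32 x 32 x 20 grid of 2.5 mm voxels, TR 2 s, 200
#' volumes in one run, baseline 1000 with Gaussian noise sd 10 (whole-brain
#' TSNR about 100), quadratic drift, one 1 mm motion spike, one variance line
#' at scale 5, and one seeded network. Artifacts can be switched off by
#' passing empty specs.
#'
#' @param dims grid size (x, y, z), each at least 16 where an anatomical
#'   phantom is requested.
#' @param voxel_size voxel edges, mm.
#' @param tr repetition time, seconds.
#' @param n_volumes total number of volumes (>= 10).
#' @param n_runs number of equal-length runs (must divide n_volumes).
#' @param baseline_mean mean in-mask baseline intensity.
#' @param noise_sd temporal noise standard deviation (> 0).
#' @param drift_amplitude,drift_order slow polynomial drift scale and order.
#' @param motion_spike_times,motion_spike_magnitudes 1-based volume indices
#'   and mm magnitudes of head-motion spikes (magnitudes >= 0).
#' @param variance_lines data.frame with columns i, j, scale: in-plane columns
#'   whose noise is multiplied by scale (> 1) across all slices.
#' @param networks list of lists with elements seed (1-based voxel triple),
#'   radius (voxels) and amplitude (signal units) for seeded networks.
#' @param roi_tsnr optional named numeric of per-ROI target TSNR (names are
#'   atlas labels as characters).
#' @param hrf response kernel for stimulus timing: "gamma", "block" or
#'   "identity".
#' @param stim_onsets,stim_durations per-stimulus lists of onset seconds and
#'   durations.
#' @param flip mirror the EPI across the left-right axis (for flip-check
#'   tests).
#' @param presteady_n,presteady_factor number of initial volumes inflated by
#'   the given factor (pre-steady-state magnetization artifact).
#' @param seed RNG seed; all generation is a pure function of (spec, seed).
#' @return A list of class \code{SimSpec}.
#' @export
simSpec <- function(dims = c(32L, 32L, 20L), voxel_size = c(2.5, 2.5, 2.5),
                    tr = 2, n_volumes = 200L, n_runs = 1L,
                    baseline_mean = 1000, noise_sd = 10,
                    drift_amplitude = 10, drift_order = 2L,
                    motion_spike_times = c(60L),
                    motion_spike_magnitudes = c(1.0),
                    variance_lines = data.frame(i = 10L, j = 22L, scale = 5),
                    networks = list(list(seed = c(16L, 10L, 10L), radius = 3,
                                         amplitude = 20)),
                    roi_tsnr = NULL,
                    hrf = c("gamma", "block", "identity"),
                    stim_onsets = list(), stim_durations = list(),
                    flip = FALSE, presteady_n = 0L, presteady_factor = 1.15,
                    seed = 1L) {
  hrf <- match.arg(hrf)
  if (n_volumes < 10L) stopf("n_volumes must be >= 10")
  if (noise_sd <= 0) stopf("noise_sd must be > 0")
  if (n_volumes %% n_runs != 0L) stopf("n_runs must divide n_volumes")
  if (length(motion_spike_times) &&
      any(motion_spike_times > n_volumes))
    stopf("spike times must be < n_volumes")
  if (length(motion_spike_magnitudes) &&
      any(motion_spike_magnitudes < 0))
    stopf("spike magnitudes must be >= 0")
  if (nrow(variance_lines) && any(variance_lines$scale <= 1))
    stopf("variance-line scale factors must be > 1")
  spec <- list(dims = as.integer(dims), voxel_size = voxel_size, tr = tr,
               n_volumes = as.integer(n_volumes), n_runs = as.integer(n_runs),
               baseline_mean = baseline_mean, noise_sd = noise_sd,
               drift_amplitude = drift_amplitude,
               drift_order = as.integer(drift_order),
               motion_spike_times = as.integer(motion_spike_times),
               motion_spike_magnitudes = motion_spike_magnitudes,
               variance_lines = variance_lines, networks = networks,
               roi_tsnr = roi_tsnr, hrf = hrf, stim_onsets = stim_onsets,
               stim_durations = stim_durations, flip = flip,
               presteady_n = as.integer(presteady_n),
               presteady_factor = presteady_factor, seed = as.integer(seed))
  class(spec) <- "SimSpec"
  spec
}

run_lengths_of <- function(spec) rep(spec$n_volumes %/% spec$n_runs,
                                     spec$n_runs)

# Normalized ellipsoid radius for every voxel of a grid.
.ellipsoid_rho <- function(dims, semi_frac = 0.40) {
  ctr <- (dims + 1) / 2
  semi <- semi_frac * dims
  i <- (seq_len(dims[1]) - ctr[1]) / semi[1]
  j <- (seq_len(dims[2]) - ctr[2]) / semi[2]
  k <- (seq_len(dims[3]) - ctr[3]) / semi[3]
  sqrt(outer(outer(i^2, j^2, "+"), k^2, "+"))
}

#' Generate the anatomical phantom and its brain mask
#'
#' An ellipsoidal "brain" with three concentric intensity tissues, a
#' deliberate single-hemisphere asymmetry lobe (so left-right flips are
#' detectable), and a seeded intensity texture. The mask is the support of the
#' ellipsoid plus the lobe.
#'
#' @param spec a \code{\link{simSpec}}.
#' @return list with elements \code{anat} (\linkS4class{Dataset3D}) and
#'   \code{mask} (\linkS4class{Mask3D}).
#' @export
makePhantomAnat <- function(spec = simSpec()) {
  dims <- spec$dims
  if (any(dims < 16L)) stopf("anatomical phantom needs dims >= 16 per axis")
  rho <- .ellipsoid_rho(dims)
  vol <- array(0, dims)
  vol[rho <= 1] <- 400
  vol[rho <= 0.8] <- 700
  vol[rho <= 0.45] <- 1000
  # asymmetry lobe: small bright sphere on the +x (right) hemisphere
  ctr <- (dims + 1) / 2
  lobe_ctr <- c(ctr[1] + 0.62 * 0.40 * dims[1], ctr[2], ctr[3])
  lobe_r <- max(2.5, 0.10 * dims[1])
  i <- seq_len(dims[1]); j <- seq_len(dims[2]); k <- seq_len(dims[3])
  d2 <- outer(outer((i - lobe_ctr[1])^2, (j - lobe_ctr[2])^2, "+"),
              (k - lobe_ctr[3])^2, "+")
  lobe <- d2 <= lobe_r^2
  vol[lobe] <- 1300
  msk <- (rho <= 1) | lobe
  vol <- with_seed(spec$seed + 101L, {
    vol + array(stats::rnorm(prod(dims), sd = 15), dims) * msk
  })
  aff <- .default_affine(spec$voxel_size, dims)
  list(anat = dataset3D(vol, spec$voxel_size, aff),
       mask = mask3D(msk, spec$voxel_size, aff))
}

#' Partition a mask into a toy atlas of contiguous ROIs
#'
#' Seeds are placed by k-means over in-mask coordinates and regions are grown
#' by round-robin face-connected flood fill, giving disjoint, contiguous,
#' nonempty integer labels (0 = background).
#'
#' @param mask a \linkS4class{Mask3D}.
#' @param n_roi number of regions (>= 2).
#' @param max_size per-ROI voxel cap.
#' @param seed RNG seed for the k-means placement.
#' @return A \linkS4class{Dataset3D} of integer labels.
#' @export
makeToyAtlas <- function(mask, n_roi = 4L, max_size = 150L, seed = 1L) {
  if (n_roi < 2L) stopf("n_roi must be >= 2")
  dims <- dim(mask@values)
  sel <- which(mask@values > 0)
  if (length(sel) < 8L * n_roi) stopf("mask too small to host %d ROIs", n_roi)
  coords <- arrayInd(sel, dims)
  km <- with_seed(seed, stats::kmeans(coords, centers = n_roi, nstart = 3L))
  labels <- array(0L, dims)
  frontiers <- vector("list", n_roi)
  sizes <- integer(n_roi)
  for (r in seq_len(n_roi)) {
    # snap each center to the nearest unassigned in-mask voxel
    d2 <- rowSums(sweep(coords, 2L, km$centers[r, ])^2)
    ord <- order(d2)
    for (o in ord) if (labels[sel[o]] == 0L) {
      labels[sel[o]] <- r
      frontiers[[r]] <- sel[o]
      sizes[r] <- 1L
      break
    }
  }
  nxyz <- c(1L, dims[1], dims[1] * dims[2])
  active <- rep(TRUE, n_roi)
  while (any(active)) {
    for (r in which(active)) {
      if (!length(frontiers[[r]]) || sizes[r] >= max_size) {
        active[r] <- FALSE
        next
      }
      newf <- integer()
      for (v in frontiers[[r]]) {
        ijk <- arrayInd(v, dims)[1, ]
        for (ax in 1:3) for (s in c(-1L, 1L)) {
          p <- ijk[ax] + s
          if (p < 1L || p > dims[ax]) next
          nb <- v + s * nxyz[ax]
          if (mask@values[nb] > 0 && labels[nb] == 0L &&
              sizes[r] < max_size) {
            labels[nb] <- r
            sizes[r] <- sizes[r] + 1L
            newf <- c(newf, nb)
          }
        }
      }
      frontiers[[r]] <- newf
    }
  }
  dataset3D(labels, mask@voxelSize, mask@affine)
}

#' Simulate rigid-body motion parameter traces
#'
#' Six columns (3 rotations in degrees, 3 translations in mm): a smooth
#' low-amplitude baseline plus the spec's spikes, injected into the
#' x-translation column for one volume each.
#'
#' @param spec a \code{\link{simSpec}}.
#' @return A \linkS4class{Matrix1D} with T rows and 6 labeled columns.
#' @export
simulateMotionParams <- function(spec = simSpec()) {
  T <- spec$n_volumes
  mp <- with_seed(spec$seed + 202L, {
    m <- matrix(0, T, 6L)
    for (c0 in 1:6) {
      ar <- stats::filter(stats::rnorm(T, sd = 0.005), 0.95, method =
                            "recursive")
      m[, c0] <- as.numeric(ar) +
        0.05 * legendre_basis(T, 2L)[, 2:3] %*% stats::rnorm(2L)
    }
    m
  })
  for (s in seq_along(spec$motion_spike_times))
    mp[spec$motion_spike_times[s], 4L] <-
      mp[spec$motion_spike_times[s], 4L] + spec$motion_spike_magnitudes[s]
  matrix1D(mp, column_labels = c("roll", "pitch", "yaw",
                                 "dS", "dL", "dP"))
}

# Analytic prediction of which volumes the default censor rule removes,
# computed from the spec alone (never by running the detectors): a motion
# spike of magnitude above the enorm limit at t censors {t-1, t, t+1} within
# its run (forward differences implicate both members of each pair and the
# previous-volume extension is on by default); volumes carrying an injected
# intensity perturbation (motion spikes, pre-steady-state inflation) exceed
# the outlier-fraction limit and censor {t}.
.expected_censored <- function(spec, enorm_limit = 0.3) {
  rl <- run_lengths_of(spec)
  run_start <- cumsum(c(1L, rl))[seq_along(rl)]
  run_end <- cumsum(rl)
  cens <- integer()
  for (s in seq_along(spec$motion_spike_times)) {
    t <- spec$motion_spike_times[s]
    if (spec$motion_spike_magnitudes[s] <= enorm_limit) next
    run <- which(t >= run_start & t <= run_end)
    lo <- run_start[run]; hi <- run_end[run]
    if (t > lo) cens <- c(cens, t - 1L, t)       # e[t] over limit
    if (t < hi) cens <- c(cens, t, t + 1L)       # e[t+1] over limit
  }
  cens <- c(cens, spec$motion_spike_times)       # intensity outlier at t
  if (spec$presteady_n > 0L) cens <- c(cens, seq_len(spec$presteady_n))
  sort(unique(cens))
}

#' Simulate the EPI phantom with ground truth
#'
#' Baseline (anatomy-weighted), polynomial drift, Gaussian noise, and every
#' artifact requested in the spec: motion-spike volumes get a 1-voxel shift
#' plus a 5 percent intensity perturbation, listed in-plane columns get their
#' noise multiplied through all slices, network voxels share a smooth time
#' course, per-ROI noise is scaled to hit TSNR targets, and the first
#' \code{presteady_n} volumes are inflated. The returned
#' \code{TruthRecord} lists every injection for detector validation.
#'
#' @param spec a \code{\link{simSpec}}.
#' @param anat optional anatomical phantom list from
#'   \code{\link{makePhantomAnat}} (regenerated from the spec when missing).
#' @param atlas optional \linkS4class{Dataset3D} label volume, required when
#'   \code{spec$roi_tsnr} is set.
#' @return list with elements \code{epi} (\linkS4class{Dataset4D}),
#'   \code{truth} (class \code{TruthRecord}), \code{mask}, \code{anat}.
#' @export
simulateEpi <- function(spec = simSpec(), anat = NULL, atlas = NULL) {
  if (is.null(anat)) anat <- makePhantomAnat(spec)
  dims <- spec$dims
  if (!all(dim(anat$anat@values) == dims)) stopf("anat grid mismatch")
  for (nw in spec$networks)
    if (nw$radius >= min(dims)) stopf("network radius exceeds grid")
  T <- spec$n_volumes
  msk <- anat$mask@values > 0
  nvox <- prod(dims)

  base <- array(spec$baseline_mean * 0.02, dims)
  base[msk] <- spec$baseline_mean * anat$anat@values[msk] /
    mean(anat$anat@values[msk])

  sdmap <- array(spec$noise_sd, dims)
  if (!is.null(spec$roi_tsnr)) {
    if (is.null(atlas)) stopf("roi_tsnr targets require an atlas")
    for (lab in names(spec$roi_tsnr)) {
      selr <- atlas@values == as.integer(lab)
      sdmap[selr] <- base[selr] / spec$roi_tsnr[[lab]]
    }
  }

  rl <- run_lengths_of(spec)
  seeds_rec <- list()
  arr <- with_seed(spec$seed, {
    eps <- matrix(stats::rnorm(nvox * T), nvox, T)
    if (nrow(spec$variance_lines)) for (r in seq_len(nrow(spec$variance_lines))) {
      ii <- spec$variance_lines$i[r]; jj <- spec$variance_lines$j[r]
      col_idx <- ii + (jj - 1L) * dims[1] +
        (seq_len(dims[3]) - 1L) * dims[1] * dims[2]
      eps[col_idx, ] <- eps[col_idx, ] * spec$variance_lines$scale[r]
    }
    X <- matrix(base, nvox, T) + eps * as.vector(sdmap)

    # slow drift, in-mask only, per run
    start <- 1L
    for (len in rl) {
      B <- legendre_basis(len, max(1L, spec$drift_order))[, -1L, drop = FALSE]
      cf <- stats::rnorm(ncol(B))
      drift <- spec$drift_amplitude * as.numeric(B %*% (cf / max(1e-9, sqrt(sum(cf^2)))))
      X[msk, start:(start + len - 1L)] <-
        X[msk, start:(start + len - 1L)] + rep(drift, each = sum(msk))
      start <- start + len
    }

    # seeded networks: shared smooth course on voxels within radius of seed
    if (length(spec$networks)) {
      ijk <- arrayInd(seq_len(nvox), dims)
      for (nw in spec$networks) {
        raw <- stats::rnorm(T)
        sm <- stats::filter(raw, gauss_kernel_1d(2) / sum(gauss_kernel_1d(2)),
                            sides = 2L)
        sm[is.na(sm)] <- 0
        course <- as.numeric(scale(sm))
        d2 <- (ijk[, 1] - nw$seed[1])^2 + (ijk[, 2] - nw$seed[2])^2 +
          (ijk[, 3] - nw$seed[3])^2
        vox <- which(d2 <= nw$radius^2 & as.vector(msk))
        X[vox, ] <- X[vox, ] + nw$amplitude * rep(course, each = length(vox))
        seeds_rec[[length(seeds_rec) + 1L]] <-
          list(seed = nw$seed, voxels = vox, course = course,
               amplitude = nw$amplitude)
      }
    }
    X
  })

  # pre-steady-state inflation of the initial volumes
  if (spec$presteady_n > 0L)
    arr[, seq_len(spec$presteady_n)] <- arr[, seq_len(spec$presteady_n)] *
      spec$presteady_factor

  # motion-spike volumes: 1-voxel x-shift plus intensity perturbation
  for (t in spec$motion_spike_times) {
    vol <- array(arr[, t], dims)
    shifted <- vol[c(dims[1], seq_len(dims[1] - 1L)), , , drop = FALSE]
    arr[, t] <- as.vector(shifted) * 1.05
  }

  arr4 <- array(arr, c(dims, T))
  if (spec$flip) arr4 <- arr4[rev(seq_len(dims[1])), , , , drop = FALSE]

  epi <- dataset4D(arr4, spec$voxel_size, spec$tr,
                   affine = anat$anat@affine, run_lengths = rl)
  truth <- list(
    motion = simulateMotionParams(spec),
    expected_censored = .expected_censored(spec),
    variance_line_cols = spec$variance_lines,
    network_seeds = seeds_rec,
    roi_tsnr = spec$roi_tsnr,
    flip_applied = spec$flip,
    presteady_n = spec$presteady_n,
    rng_seed = spec$seed)
  class(truth) <- "TruthRecord"
  list(epi = epi, truth = truth, mask = anat$mask, anat = anat$anat)
}

#' Write stimulus timing as text (one row of onset seconds per run)
#'
#' @param onsets_per_run list with one numeric vector of onset seconds per run.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStimTiming <- function(onsets_per_run, path) {
  writeLines(vapply(onsets_per_run, function(o)
    if (length(o)) paste(fmt6(o), collapse = " ") else "*", character(1)),
    path)
  invisible(path)
}

#' Serialize a TruthRecord to JSON
#'
#' @param truth a \code{TruthRecord} from \code{\link{simulateEpi}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTruthRecord <- function(truth, path) {
  out <- list(
    expected_censored = truth$expected_censored,
    variance_line_cols = truth$variance_line_cols,
    network_seeds = lapply(truth$network_seeds, function(s)
      list(seed = s$seed, n_voxels = length(s$voxels),
           amplitude = s$amplitude)),
    roi_tsnr = truth$roi_tsnr,
    flip_applied = truth$flip_applied,
    presteady_n = truth$presteady_n,
    rng_seed = truth$rng_seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
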