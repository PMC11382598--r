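# Internal numerical helpers shared across modules.

# Evaluate a fixed expression with a temporary RNG state so generators are pure
# functions of (spec, seed) without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Legendre polynomial basis P_0..P_order sampled on n points over [-1, 1].
legendre_basis <- function(n, order) {
  x <- if (n == 1L) 0 else seq(-1, 1, length.out = n)
  B <- matrix(0, n, order + 1L)
  B[, 1L] <- 1
  if (order >= 1L) B[, 2L] <- x
  if (order >= 2L) for (k in 2L:order)
    B[, k + 1L] <- ((2 * k - 1) * x * B[, k] - (k - 1) * B[, k - 1L]) / k
  B
}

# Detrend order used by the outlier and variance-line detectors:
# 1 + floor(run duration in seconds / 150).
detrend_order <- function(n_volumes, tr) 1L + floor(n_volumes * tr / 150)

# Residualize the columns of Y (time x series) against a Legendre basis,
# independently within each run.
detrend_runs <- function(Y, run_lengths, tr, order = NULL) {
  Y <- as.matrix(Y)
  out <- Y
  start <- 1L
  for (len in run_lengths) {
    idx <- start:(start + len - 1L)
    ord <- if (is.null(order)) detrend_order(len, tr) else order
    ord <- min(ord, len - 1L)
    B <- legendre_basis(len, ord)
    Q <- qr.Q(qr(B))
    out[idx, ] <- Y[idx, , drop = FALSE] -
      Q %*% crossprod(Q, Y[idx, , drop = FALSE])
    start <- start + len
  }
  out
}

# 0-based voxel index (vector or 3-row matrix) to world mm via an affine.
index_to_mm <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = TRUE]
}

# World mm to nearest 0-based voxel index.
mm_to_index <- function(affine, mm) {
  round(solve(affine) %*% c(mm, 1))[1:3]
}

# Which array axis is the world left-right axis (largest |x| direction cosine).
lr_axis <- function(affine) which.max(abs(affine[1L, 1:3]))

# Separable truncated-Gaussian smoothing of a 3D array. fwhm in mm, one value
# per axis after division by voxel size. Returns the *unnormalized* weighted
# sum (kernel weights are raw exp(-d^2/2s^2)), so that ratios of two smoothed
# fields renormalize exactly.
gauss_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(3.5 * sigma_vox))
  d <- -r:r
  exp(-d^2 / (2 * sigma_vox^2))
}

# Band matrix applying a symmetric 1D kernel (zero boundary) along one axis.
band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    lo <- max(1L, j - r); hi <- min(n, j + r)
    M[lo:hi, j] <- kernel[(lo - j + r + 1L):(hi - j + r + 1L)]
  }
  M
}

smooth3d <- function(vol, sigma_vox) {
  d <- dim(vol)
  k1 <- gauss_kernel_1d(sigma_vox[1]); k2 <- gauss_kernel_1d(sigma_vox[2])
  k3 <- gauss_kernel_1d(sigma_vox[3])
  M1 <- band_matrix(d[1], k1); M2 <- band_matrix(d[2], k2)
  M3 <- band_matrix(d[3], k3)
  v <- array(M1 %*% matrix(vol, d[1], d[2] * d[3]), d)
  v <- aperm(array(M2 %*% matrix(aperm(v, c(2, 1, 3)), d[2], d[1] * d[3]),
                   c(d[2], d[1], d[3])), c(2, 1, 3))
  aperm(array(M3 %*% matrix(aperm(v, c(3, 1, 2)), d[3], d[1] * d[2]),
              c(d[3], d[1], d[2])), c(2, 3, 1))
}

# Flatten a Dataset4D into a T x N matrix over in-mask voxels.
mask_series <- function(dset, mask) {
  d <- dim(dset@values)
  sel <- which(mask@values > 0)
  t(matrix(dset@values, prod(d[1:3]), d[4])[sel, , drop = FALSE])
}

# Format a number with up to 6 significant digits, the printed precision of
# review files.
fmt6 <- function(x) {
  if (is.character(x)) return(x)
  vapply(x, function(v) {
    if (v == floor(v) && abs(v) < 1e15) format(v, scientific = FALSE)
    else format(signif(v, 6), scientific = FALSE)
  }, character(1))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
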