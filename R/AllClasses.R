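#' @import methods
NULL

#' Gridded 4D EPI time series
#'
#' Carrier of all 4D image math in the package. Values are indexed (x, y, z, t);
#' voxel sizes are in mm, the repetition time in seconds, and \code{affine} maps
#' 0-based grid indices to world mm coordinates.
#'
#' @slot values 4D numeric array indexed (x, y, z, t).
#' @slot voxelSize length-3 numeric, voxel edge lengths in mm.
#' @slot tr repetition time in seconds.
#' @slot affine 4x4 grid-to-world map (0-based voxel index to mm).
#' @slot runLengths integer vector of per-run volume counts; must sum to the
#'   time dimension.
#' @export
setClass("Dataset4D",
  representation(values = "array", voxelSize = "numeric", tr = "numeric",
                 affine = "matrix", runLengths = "integer"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 4L) return("values must be a 4D array")
    if (any(d < 1L)) return("all dims must be >= 1")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0)) return("voxel sizes must be 3 positive reals")
    if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
      return("tr must be a positive scalar")
    if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
    if (abs(det(object@affine)) < .Machine$double.eps)
      return("affine must have nonzero determinant")
    if (sum(object@runLengths) != d[4L])
      return("sum(runLengths) must equal the time dimension")
    if (any(object@runLengths < 1L)) return("run lengths must be >= 1")
    TRUE
  })

#' Gridded 3D volume
#'
#' @slot values 3D numeric array.
#' @slot voxelSize length-3 numeric (mm).
#' @slot affine 4x4 grid-to-world map.
#' @export
setClass("Dataset3D",
  representation(values = "array", voxelSize = "numeric", affine = "matrix"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("values must be a 3D array")
    if (any(d < 1L)) return("all dims must be >= 1")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxel sizes must be 3 positive reals")
    if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
    TRUE
  })

#' Binary 3D mask on a dataset grid
#'
#' @slot values 3D array with values in {0, 1}.
#' @slot voxelSize length-3 numeric (mm).
#' @slot affine 4x4 grid-to-world map.
#' @export
setClass("Mask3D",
  representation(values = "array", voxelSize = "numeric", affine = "matrix"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("values must be a 3D array")
    if (!all(object@values %in% c(0, 1))) return("mask values must be 0 or 1")
    TRUE
  })

#' Whitespace-separated numeric matrix (AFNI-style \code{.1D} carrier)
#'
#' Rows are time points, columns are series. \code{columnLabels} may be empty.
#'
#' @slot values numeric matrix.
#' @slot columnLabels character vector, either empty or one label per column.
#' @export
setClass("Matrix1D",
  representation(values = "matrix", columnLabels = "character"),
  validity = function(object) {
    if (length(object@columnLabels) &&
        length(object@columnLabels) != ncol(object@values))
      return("columnLabels length must match column count")
    TRUE
  })

#' Ordered label -> value review record
#'
#' The unit of single-subject review and group tabulation: an ordered mapping
#' from quantity labels to scalar, string, or list-of-scalar values.
#'
#' @slot entries named list; names unique, numeric values finite.
#' @export
setClass("ReviewDict",
  representation(entries = "list"),
  validity = function(object) {
    nm <- names(object@entries)
    if (length(object@entries) && (is.null(nm) || any(nm == "")))
      return("all entries must be labeled")
    if (anyDuplicated(nm)) return(paste("duplicate label:",
                                        nm[duplicated(nm)][1L]))
    for (v in object@entries)
      if (is.numeric(v) && any(!is.finite(v)))
        return("numeric values must be finite")
    TRUE
  })

#' Per-volume keep/censor decision
#'
#' @slot keep length-T binary vector; 1 = keep, 0 = censored.
#' @slot limits named list with \code{enorm_limit} (mm-equivalent) and
#'   \code{outlier_limit} (fraction), both > 0.
#' @export
setClass("CensorVector",
  representation(keep = "numeric", limits = "list"),
  validity = function(object) {
    if (!all(object@keep %in% c(0, 1))) return("keep must be binary")
    lim <- object@limits
    if (!all(c("enorm_limit", "outlier_limit") %in% names(lim)))
      return("limits must name enorm_limit and outlier_limit")
    if (any(unlist(lim) <= 0)) return("limits must be positive")
    TRUE
  })

#' Voxelwise correlation map
#'
#' @slot values 3D array of correlations in [-1, 1] (0 outside the mask or at
#'   zero-variance voxels).
#' @slot kind one of "corr_brain", "radcor", "seed".
#' @slot seed optional mm coordinate (length 3, or empty).
#' @slot stage processing-stage label (e.g. "tcat", "volreg", "regress").
#' @slot thresholds render metadata: transparent and range |r| bounds.
#' @export
setClass("CorrMap",
  representation(values = "array", kind = "character", seed = "numeric",
                 stage = "character", thresholds = "list"),
  validity = function(object) {
    if (!object@kind %in% c("corr_brain", "radcor", "seed"))
      return("kind must be corr_brain, radcor or seed")
    if (max(abs(object@values), na.rm = TRUE) > 1 + 1e-8)
      return("|values| must be <= 1")
    TRUE
  })

#' Voxelwise temporal signal-to-noise ratio map
#'
#' @slot values 3D array, mean(signal)/sd(noise) per voxel (0 where sd = 0).
#' @slot stage "volreg" or "regress".
#' @slot signalSource,noiseSource labels of the datasets used.
#' @export
setClass("TsnrMap",
  representation(values = "array", stage = "character",
                 signalSource = "character", noiseSource = "character"),
  validity = function(object) {
    if (!object@stage %in% c("volreg", "regress"))
      return("stage must be volreg or regress")
    TRUE
  })

#' Group review table
#'
#' One review dict per subject, with a stable union column order (first-seen).
#'
#' @slot subjects character subject ids, one per row.
#' @slot labels character column labels in first-seen order.
#' @slot rows list of named lists (one per subject); missing values absent.
#' @export
setClass("GroupTable",
  representation(subjects = "character", labels = "character", rows = "list"),
  validity = function(object) {
    if (length(object@subjects) != length(object@rows))
      return("one row per subject required")
    TRUE
  })

# ---- constructors ----------------------------------------------------------

.default_affine <- function(voxel_size, dims) {
  aff <- diag(c(voxel_size, 1))
  # center the grid at world origin, RAS-ish: +x = right
  aff[1:3, 4] <- -voxel_size * (dims[1:3] - 1) / 2
  aff
}

#' Construct a Dataset4D
#'
#' @param values 4D array (x, y, z, t).
#' @param voxel_size mm triple.
#' @param tr repetition time, seconds.
#' @param affine optional 4x4 grid-to-world map; default centers the grid.
#' @param run_lengths per-run volume counts; default a single run.
#' @return A \linkS4class{Dataset4D}.
#' @export
dataset4D <- function(values, voxel_size = c(1, 1, 1), tr = 1, affine = NULL,
                      run_lengths = NULL) {
  values <- as.array(values)
  if (is.null(affine)) affine <- .default_affine(voxel_size, dim(values))
  if (is.null(run_lengths)) run_lengths <- dim(values)[4L]
  new("Dataset4D", values = values, voxelSize = as.numeric(voxel_size),
      tr = as.numeric(tr), affine = affine,
      runLengths = as.integer(run_lengths))
}

#' Construct a Dataset3D
#' @param values 3D array.
#' @param voxel_size mm triple.
#' @param affine optional 4x4 map; default centers the grid.
#' @return A \linkS4class{Dataset3D}.
#' @export
dataset3D <- function(values, voxel_size = c(1, 1, 1), affine = NULL) {
  values <- as.array(values)
  if (is.null(affine)) affine <- .default_affine(voxel_size, dim(values))
  new("Dataset3D", values = values, voxelSize = as.numeric(voxel_size),
      affine = affine)
}

#' Construct a Mask3D
#' @param values 3D array of 0/1 (logical accepted).
#' @param voxel_size mm triple.
#' @param affine optional 4x4 map.
#' @return A \linkS4class{Mask3D}.
#' @export
mask3D <- function(values, voxel_size = c(1, 1, 1), affine = NULL) {
  values <- as.array(values) * 1
  if (is.null(affine)) affine <- .default_affine(voxel_size, dim(values))
  new("Mask3D", values = values, voxelSize = as.numeric(voxel_size),
      affine = affine)
}

#' Construct a Matrix1D
#' @param values numeric matrix (rows = time).
#' @param column_labels optional character labels.
#' @return A \linkS4class{Matrix1D}.
#' @export
matrix1D <- function(values, column_labels = character()) {
  new("Matrix1D", values = as.matrix(values),
      columnLabels = as.character(column_labels))
}

#' Construct a ReviewDict
#' @param entries named list of scalar/string/list-of-scalar values.
#' @return A \linkS4class{ReviewDict}.
#' @export
reviewDict <- function(entries = list()) new("ReviewDict", entries = entries)

#' Construct a CensorVector
#' @param keep binary keep vector (1 = keep).
#' @param enorm_limit,outlier_limit positive censor limits.
#' @return A \linkS4class{CensorVector}.
#' @export
censorVector <- function(keep, enorm_limit = 0.3, outlier_limit = 0.05) {
  new("CensorVector", keep = as.numeric(keep),
      limits = list(enorm_limit = enorm_limit, outlier_limit = outlier_limit))
}

# ---- accessors -------------------------------------------------------------

#' @rdname accessors
#' @param object an fmriqc data object.
#' @export
setGeneric("values", function(object) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("affineMat", function(object) standardGeneric("affineMat"))
#' @rdname accessors
#' @export
setGeneric("repTime", function(object) standardGeneric("repTime"))
#' @rdname accessors
#' @export
setGeneric("runLengths", function(object) standardGeneric("runLengths"))
#' @rdname accessors
#' @export
setGeneric("entries", function(object) standardGeneric("entries"))

#' Accessors for fmriqc data objects
#' @name accessors
#' @return The corresponding slot value.
NULL

#' @rdname accessors
setMethod("values", "Dataset4D", function(object) object@values)
#' @rdname accessors
setMethod("values", "Dataset3D", function(object) object@values)
#' @rdname accessors
setMethod("values", "Mask3D", function(object) object@values)
#' @rdname accessors
setMethod("values", "Matrix1D", function(object) object@values)
#' @rdname accessors
setMethod("values", "CorrMap", function(object) object@values)
#' @rdname accessors
setMethod("values", "TsnrMap", function(object) object@values)
#' @rdname accessors
setMethod("voxelSize", "Dataset4D", function(object) object@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "Dataset3D", function(object) object@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "Mask3D", function(object) object@voxelSize)
#' @rdname accessors
setMethod("affineMat", "Dataset4D", function(object) object@affine)
#' @rdname accessors
setMethod("affineMat", "Dataset3D", function(object) object@affine)
#' @rdname accessors
setMethod("affineMat", "Mask3D", function(object) object@affine)
#' @rdname accessors
setMethod("repTime", "Dataset4D", function(object) object@tr)
#' @rdname accessors
setMethod("runLengths", "Dataset4D", function(object) object@runLengths)
#' @rdname accessors
setMethod("entries", "ReviewDict", function(object) object@entries)

# ---- show methods ----------------------------------------------------------

setMethod("show", "Dataset4D", function(object) {
  d <- dim(object@values)
  cat(sprintf("Dataset4D: %d x %d x %d x %d, voxel %s mm, TR %g s, runs: %s\n",
              d[1], d[2], d[3], d[4],
              paste(format(object@voxelSize), collapse = " x "),
              object@tr, paste(object@runLengths, collapse = ", ")))
})

setMethod("show", "Dataset3D", function(object) {
  d <- dim(object@values)
  cat(sprintf("Dataset3D: %d x %d x %d, voxel %s mm\n", d[1], d[2], d[3],
              paste(format(object@voxelSize), collapse = " x ")))
})

setMethod("show", "Mask3D", function(object) {
  d <- dim(object@values)
  cat(sprintf("Mask3D: %d x %d x %d, %d voxels in mask\n", d[1], d[2], d[3],
              sum(object@values)))
})

setMethod("show", "Matrix1D", function(object) {
  cat(sprintf("Matrix1D: %d rows x %d columns%s\n", nrow(object@values),
              ncol(object@values),
              if (length(object@columnLabels))
                paste0(" (", paste(object@columnLabels, collapse = ", "), ")")
              else ""))
})

setMethod("show", "ReviewDict", function(object) {
  cat(sprintf("ReviewDict with %d entries\n", length(object@entries)))
  for (nm in utils::head(names(object@entries), 12L))
    cat(sprintf("  %s : %s\n", nm,
                paste(format(object@entries[[nm]], digits = 6),
                      collapse = " ")))
  if (length(object@entries) > 12L) cat("  ...\n")
})

setMethod("show", "CensorVector", function(object) {
  cat(sprintf("CensorVector: %d volumes, %d censored (enorm > %g or outlier > %g)\n",
              length(object@keep), sum(object@keep == 0),
              object@limits$enorm_limit, object@limits$outlier_limit))
})

setMethod("show", "CorrMap", function(object) {
  cat(sprintf("CorrMap (%s, stage %s): range [%.3f, %.3f]\n", object@kind,
              object@stage, min(object@values), max(object@values)))
})

setMethod("show", "TsnrMap", function(object) {
  cat(sprintf("TsnrMap (stage %s): signal=%s noise=%s, max %.1f\n",
              object@stage, object@signalSource, object@noiseSource,
              max(object@values)))
})

setMethod("show", "GroupTable", function(object) {
  cat(sprintf("GroupTable: %d subjects x %d columns\n",
              length(object@subjects), length(object@labels)))
})
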