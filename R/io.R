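# Readers/writers: NIfTI-1 volumes (via RNifti), whitespace .1D matrices,
# and colon-separated / JSON review dictionaries.

#' Read a NIfTI-1 volume
#'
#' 4D files yield a \linkS4class{Dataset4D} (TR taken from the header time
#' step; a zero or missing time step falls back to 1.0 s with a warning), 3D
#' files a \linkS4class{Dataset3D}.
#'
#' @param path path to a .nii or .nii.gz file.
#' @return A \linkS4class{Dataset4D} or \linkS4class{Dataset3D}.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf(
                    "not a readable NIfTI-1 file (%s): %s", path,
                    conditionMessage(e)))
  pd <- RNifti::pixdim(img)
  if (any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stopf("format error in %s: non-finite or nonpositive voxel sizes", path)
  aff <- unclass(RNifti::xform(img))
  arr <- array(as.vector(img), dim(img))
  nd <- length(dim(arr))
  if (nd == 3L) {
    dataset3D(arr, voxel_size = pd[1:3], affine = aff)
  } else if (nd == 4L) {
    tr <- if (length(pd) >= 4L) pd[4L] else 0
    if (!is.finite(tr) || tr <= 0) {
      warnf("%s: header time step is %s; defaulting TR to 1.0 s", path,
            format(tr))
      tr <- 1.0
    }
    dataset4D(arr, voxel_size = pd[1:3], tr = tr, affine = aff)
  } else stopf("format error in %s: %d-dimensional image unsupported", path, nd)
}

#' Write a dataset to NIfTI-1
#'
#' @param dset a \linkS4class{Dataset4D}, \linkS4class{Dataset3D} or
#'   \linkS4class{Mask3D}.
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(dset, path) {
  arr <- dset@values
  tr <- if (is(dset, "Dataset4D")) dset@tr else 1
  vs <- dset@voxelSize
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vs, rep(tr, max(0L, length(dim(arr)) - 3L)))
  RNifti::sform(img) <- structure(dset@affine, code = 2L)
  RNifti::qform(img) <- structure(dset@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a whitespace-separated .1D matrix
#'
#' Lines starting with \code{#} are comments; a comment of the form
#' \code{# ColumnLabels = a ; b} supplies column labels.
#'
#' @param path text file path.
#' @return A \linkS4class{Matrix1D}; an empty file yields 0 rows.
#' @export
readMatrix1D <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  labels <- character()
  data_rows <- list()
  width <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      if (grepl("ColumnLabels", ln)) {
        rhs <- sub(".*=", "", ln)
        rhs <- gsub("\"", "", rhs)
        labels <- trimws(strsplit(rhs, ";")[[1L]])
      }
      next
    }
    toks <- strsplit(ln, "[[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    if (any(is.na(vals)))
      stopf("parse error at line %d of %s: non-numeric token '%s'", i, path,
            toks[which(is.na(vals))[1L]])
    if (is.na(width)) width <- length(vals)
    else if (length(vals) != width)
      stopf("parse error at line %d of %s: %d tokens, expected %d", i, path,
            length(vals), width)
    data_rows[[length(data_rows) + 1L]] <- vals
  }
  m <- if (length(data_rows)) do.call(rbind, data_rows)
  else matrix(numeric(0), 0L, max(0L, width, na.rm = TRUE))
  matrix1D(m, column_labels = labels)
}

#' Write a Matrix1D as whitespace-separated text
#'
#' @param m a \linkS4class{Matrix1D}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMatrix1D <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(m@columnLabels))
    writeLines(sprintf("# ColumnLabels = %s",
                       paste(m@columnLabels, collapse = " ; ")), con)
  if (nrow(m@values))
    writeLines(apply(m@values, 1L, function(r)
      paste(fmt6(r), collapse = " ")), con)
  invisible(path)
}

.parse_review_value <- function(txt) {
  toks <- strsplit(trimws(txt), "[[:space:]]+")[[1L]]
  if (!length(toks)) return("")
  vals <- suppressWarnings(as.numeric(toks))
  if (!any(is.na(vals))) {
    if (length(vals) == 1L) vals else vals
  } else trimws(txt)
}

#' Read a review dictionary
#'
#' @param path file path.
#' @param dialect "colon" for \code{label : value} lines, "json" for a flat
#'   JSON object.
#' @return A \linkS4class{ReviewDict} preserving file order.
#' @export
readReviewDict <- function(path, dialect = c("colon", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "json") {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    ent <- lapply(obj, function(v) if (is.numeric(v)) as.numeric(v) else v)
    if (anyDuplicated(names(ent)))
      stopf("duplicate label in %s: %s", path,
            names(ent)[duplicated(names(ent))][1L])
    return(reviewDict(ent))
  }
  lines <- readLines(path, warn = FALSE)
  ent <- list()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    pos <- regexpr(":", ln, fixed = TRUE)
    if (pos < 0) next
    label <- trimws(substr(ln, 1L, pos - 1L))
    value <- .parse_review_value(substr(ln, pos + 1L, nchar(ln)))
    if (label %in% names(ent))
      stopf("duplicate label in %s: '%s'", path, label)
    ent[[label]] <- value
  }
  reviewDict(ent)
}

#' Write a review dictionary
#'
#' Numeric values are written with up to 6 significant digits in both
#' dialects, so the two serializations of one dict compare equal after
#' reading back.
#'
#' @param rd a \linkS4class{ReviewDict}.
#' @param path output path.
#' @param dialect "colon" or "json".
#' @return \code{path}, invisibly.
#' @export
writeReviewDict <- function(rd, path, dialect = c("colon", "json")) {
  dialect <- match.arg(dialect)
  ent <- lapply(rd@entries, function(v)
    if (is.numeric(v)) signif(v, 6) else v)
  if (dialect == "json") {
    jsonlite::write_json(ent, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    lines <- vapply(names(ent), function(nm)
      sprintf("%s : %s", nm, paste(fmt6(ent[[nm]]), collapse = " ")),
      character(1))
    writeLines(lines, path)
  }
  invisible(path)
}
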