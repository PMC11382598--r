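# Single-subject review assembly, group tabulation, criterion-based
# outlier/keeper filtering, and the raw-header consistency scan.

#' Assemble the single-subject review dictionary
#'
#' Merges the fragments produced by the metric modules into one ordered
#' \linkS4class{ReviewDict}, using the conventional review labels where they
#' exist ("censor fraction", "degrees of freedom left", "TSNR average",
#' "global correlation (GCOR)", ...). A label collision across fragments is
#' an error.
#'
#' @param ... named lists of review entries (e.g. the output of
#'   \code{\link{censorSummary}}), merged in order.
#' @param software version string recorded with the dict.
#' @return A \linkS4class{ReviewDict}.
#' @export
buildSsReview <- function(..., software = paste("fmriqc",
                                                utils::packageVersion("fmriqc"))) {
  frags <- list(...)
  ent <- list(`software version` = as.character(software))
  for (fr in frags) {
    if (is(fr, "ReviewDict")) fr <- fr@entries
    for (nm in names(fr)) {
      if (nm %in% names(ent))
        stopf("label collision across fragments: '%s'", nm)
      ent[[nm]] <- fr[[nm]]
    }
  }
  reviewDict(ent)
}

#' Build a group table from review dictionaries
#'
#' Column order is the union of keys in first-seen order, with the subject id
#' first; a dict missing a key leaves that cell empty (rendered as a
#' sentinel, never dropped).
#'
#' @param dicts list of \linkS4class{ReviewDict}s.
#' @param subjects subject ids (default positional).
#' @return A \linkS4class{GroupTable}.
#' @export
buildGroupTable <- function(dicts, subjects = NULL) {
  if (!length(dicts)) stopf("need at least one review dict")
  if (is.null(subjects)) subjects <- sprintf("subj%03d", seq_along(dicts))
  labels <- character()
  rows <- vector("list", length(dicts))
  for (i in seq_along(dicts)) {
    e <- if (is(dicts[[i]], "ReviewDict")) dicts[[i]]@entries else dicts[[i]]
    labels <- c(labels, setdiff(names(e), labels))
    rows[[i]] <- e
  }
  new("GroupTable", subjects = subjects, labels = labels, rows = rows)
}

#' Write a group table as TSV or CSV
#'
#' List-valued cells are expanded to suffixed columns (label.1, label.2, ...);
#' missing values are written as the sentinel "NA".
#'
#' @param table a \linkS4class{GroupTable}.
#' @param path output path.
#' @param format "tsv" (default) or "csv".
#' @return \code{path}, invisibly.
#' @export
writeGroupTable <- function(table, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  widths <- vapply(table@labels, function(lb)
    max(1L, vapply(table@rows, function(r) length(r[[lb]]), integer(1))),
    integer(1))
  header <- c("subject", unlist(lapply(seq_along(table@labels), function(i) {
    if (widths[i] == 1L) table@labels[i]
    else paste0(table@labels[i], ".", seq_len(widths[i]))
  })))
  cells <- lapply(seq_along(table@subjects), function(r) {
    row <- table@rows[[r]]
    c(table@subjects[r], unlist(lapply(seq_along(table@labels), function(i) {
      v <- row[[table@labels[i]]]
      out <- rep("NA", widths[i])
      if (!is.null(v)) out[seq_along(v)] <- fmt6(v)
      out
    })))
  })
  sep <- if (format == "tsv") "\t" else ","
  writeLines(c(paste(header, collapse = sep),
               vapply(cells, paste, character(1), collapse = sep)), path)
  invisible(path)
}

#' Filtering criterion
#'
#' @param label review-dict key the criterion applies to.
#' @param op one of "VARY", "EQ", "GT", "LT", "GE", "LE", "SHOW".
#' @param value comparison value (required except for VARY and SHOW).
#' @return list of class \code{Criterion}.
#' @export
criterion <- function(label, op = c("VARY", "EQ", "GT", "LT", "GE", "LE",
                                    "SHOW"), value = NULL) {
  op <- match.arg(op)
  if (op %in% c("VARY", "SHOW")) {
    if (!is.null(value)) stopf("%s takes no comparison value", op)
  } else if (is.null(value)) stopf("%s requires a comparison value", op)
  structure(list(label = label, op = op, value = value), class = "Criterion")
}

# Elementwise criterion evaluation for one cell; any element triggering
# counts. VARY uses exact string equality and 1e-9 relative tolerance for
# reals (values round-trip through text).
.eval_criterion <- function(cell, crit, first_cell) {
  if (is.null(cell)) return(FALSE)
  switch(crit$op,
    VARY = {
      if (is.null(first_cell)) return(FALSE)
      if (length(cell) != length(first_cell)) return(TRUE)
      if (is.numeric(cell) && is.numeric(first_cell)) {
        any(abs(cell - first_cell) >
              1e-9 * pmax(abs(first_cell), 1e-300))
      } else any(as.character(cell) != as.character(first_cell))
    },
    EQ = {
      if (is.numeric(cell)) {
        v <- suppressWarnings(as.numeric(crit$value))
        if (is.na(v)) FALSE else any(cell == v)
      } else any(as.character(cell) == as.character(crit$value))
    },
    {
      if (!is.numeric(cell))
        stopf("criterion %s on '%s': cell is not numeric", crit$op,
              crit$label)
      v <- suppressWarnings(as.numeric(crit$value))
      if (is.na(v)) stopf("criterion %s on '%s': value '%s' is not numeric",
                          crit$op, crit$label, crit$value)
      switch(crit$op, GT = any(cell > v), LT = any(cell < v),
             GE = any(cell >= v), LE = any(cell <= v))
    })
}

#' Report outlier (or keeper) subjects by criteria
#'
#' A subject is an outlier when at least one non-SHOW criterion evaluates
#' true for it; \code{show_keepers} inverts the selection to subjects with no
#' true comparison. The report populates only the triggering values plus any
#' SHOW columns.
#'
#' @param table a \linkS4class{GroupTable}.
#' @param criteria list of \code{\link{criterion}}s; labels must exist in the
#'   table.
#' @param show_keepers invert the selection (default FALSE).
#' @return data.frame: subject id, then one column per criterion label (and
#'   SHOW label); non-triggering cells are empty strings.
#' @export
filterReport <- function(table, criteria, show_keepers = FALSE) {
  for (cr in criteria)
    if (!cr$label %in% table@labels)
      stopf("criterion label not in table: '%s'", cr$label)
  tests <- Filter(function(cr) cr$op != "SHOW", criteria)
  shows <- Filter(function(cr) cr$op == "SHOW", criteria)
  first_row <- table@rows[[1L]]
  hit <- matrix(FALSE, length(table@subjects), length(tests))
  for (s in seq_along(table@subjects)) for (c0 in seq_along(tests))
    hit[s, c0] <- .eval_criterion(table@rows[[s]][[tests[[c0]]$label]],
                                  tests[[c0]], first_row[[tests[[c0]]$label]])
  selected <- if (show_keepers) which(rowSums(hit) == 0L)
  else which(rowSums(hit) > 0L)
  cols <- unique(c(vapply(tests, `[[`, character(1), "label"),
                   vapply(shows, `[[`, character(1), "label")))
  out <- data.frame(subject = table@subjects[selected],
                    stringsAsFactors = FALSE)
  for (lb in cols) out[[lb]] <- character(nrow(out))
  for (ri in seq_along(selected)) {
    s <- selected[ri]
    for (c0 in seq_along(tests)) if (hit[s, c0]) {
      lb <- tests[[c0]]$label
      out[ri, lb] <- paste(fmt6(table@rows[[s]][[lb]]), collapse = " ")
    }
    for (sh in shows) {
      v <- table@rows[[s]][[sh$label]]
      out[ri, sh$label] <- if (is.null(v)) "NA"
      else paste(fmt6(v), collapse = " ")
    }
  }
  out
}

#' Scan dataset headers for basic properties and their variability
#'
#' Reads each file, records matrix dims, voxel sizes, TR, volume count,
#' orientation code, datum kind and value min/max, then builds a group table
#' and a variability report (a \code{\link{filterReport}} with a VARY
#' criterion on every property column). Unreadable files get an error row
#' and the scan continues.
#'
#' @param paths NIfTI file paths.
#' @return list with \code{table} (\linkS4class{GroupTable}) and
#'   \code{variability} (data.frame).
#' @export
gtkydScan <- function(paths) {
  if (!length(paths)) stopf("need at least one dataset")
  dicts <- list(); ids <- character()
  for (p in paths) {
    rec <- tryCatch({
      ds <- readVolume(p)
      d <- dim(ds@values)
      orient <- tryCatch(
        RNifti::orientation(RNifti::readNifti(p)),
        error = function(e) "unknown")
      list(
        "nx" = d[1], "ny" = d[2], "nz" = d[3],
        "nv" = if (length(d) >= 4L) d[4] else 1,
        "ad3" = as.numeric(signif(ds@voxelSize, 6)),
        "tr" = if (is(ds, "Dataset4D")) ds@tr else 0,
        "orient" = orient,
        "datum" = if (all(ds@values == round(ds@values))) "int" else "float",
        "min" = min(ds@values), "max" = max(ds@values))
    }, error = function(e) list("error" = conditionMessage(e)))
    dicts[[length(dicts) + 1L]] <- rec
    ids <- c(ids, basename(p))
  }
  tab <- buildGroupTable(dicts, subjects = ids)
  crits <- lapply(setdiff(tab@labels, "error"),
                  function(lb) criterion(lb, "VARY"))
  list(table = tab, variability = filterReport(tab, crits))
}
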