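# Readers and writers for FreeSurfer regional-statistics tables
# (?h.aparc.stats dialect).  Parsing is strictly column-name driven: the
# '# ColHeaders ...' comment names the columns, so any column permutation of
# a valid file parses to the identical table.  Unknown extra columns are
# ignored for forward compatibility.

#' Read a FreeSurfer aparc.stats regional statistics file
#'
#' Parses one hemisphere's cortical parcellation statistics table.  Header
#' lines begin with `#`; the `# ColHeaders` line names the whitespace
#' delimited data columns.  Columns are mapped by name, never by position,
#' and rows are re-ordered to the canonical alphabetical StructName order.
#'
#' @param path Path to the `lh.aparc.stats` / `rh.aparc.stats` file.
#' @param hemisphere `"lh"` or `"rh"`; recorded on the returned table and
#'   checked downstream when two hemispheres are assembled.
#' @return A data frame of 34 rows (regions, canonical order, StructName as
#'   row names) by 9 columns (see [morph_features()]), with attribute
#'   `hemisphere`.
#' @seealso [assemble_subject_features()], [write_aparc_stats()]
#' @export
read_aparc_stats <- function(path, hemisphere = c("lh", "rh")) {
  hemisphere <- match.arg(hemisphere)
  if (!file.exists(path)) stopf("aparc.stats file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  ch <- grep("^#\\s*ColHeaders\\b", lines, value = TRUE)
  if (length(ch) == 0L) {
    stopf("format error in %s: no '# ColHeaders' line", path)
  }
  cols <- strsplit(sub("^#\\s*ColHeaders\\s+", "", ch[[1L]]), "\\s+")[[1L]]
  needed <- c("StructName", morph_features())
  missing_cols <- setdiff(needed, cols)
  if (length(missing_cols) > 0L) {
    stopf("format error in %s: missing column(s) %s",
          path, paste(missing_cols, collapse = ", "))
  }
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(data_lines) == 0L) stopf("format error in %s: no data rows", path)
  fields <- strsplit(trimws(data_lines), "\\s+")
  bad <- which(vapply(fields, length, 0L) != length(cols))
  if (length(bad) > 0L) {
    stopf("format error in %s: row %d has %d fields, expected %d",
          path, bad[[1L]], length(fields[[bad[[1L]]]]), length(cols))
  }
  raw <- do.call(rbind, fields)
  colnames(raw) <- cols
  struct <- raw[, "StructName"]
  if (anyDuplicated(struct)) {
    stopf("parse error in %s: duplicated region(s) %s",
          path, paste(unique(struct[duplicated(struct)]), collapse = ", "))
  }
  # unknown parcels (e.g. future atlas extensions) are dropped silently
  keep <- struct %in% dk_struct_names()
  raw <- raw[keep, , drop = FALSE]
  struct <- struct[keep]
  absent <- setdiff(dk_struct_names(), struct)
  if (length(absent) > 0L) {
    stopf("parse error in %s: missing region(s) %s",
          path, paste(absent, collapse = ", "))
  }
  out <- matrix(NA_real_, nrow = length(struct), ncol = 9L,
                dimnames = list(struct, morph_features()))
  for (f in morph_features()) {
    v <- suppressWarnings(as.numeric(raw[, f]))
    if (anyNA(v)) {
      i <- which(is.na(v))[[1L]]
      stopf("value error in %s: non-numeric cell at region '%s', column '%s'",
            path, struct[[i]], f)
    }
    out[, f] <- v
  }
  out <- out[dk_struct_names(), , drop = FALSE]
  for (f in c("NumVert", "SurfArea", "GrayVol")) {
    if (any(out[, f] <= 0)) {
      stopf("value error in %s: column '%s' must be strictly positive", path, f)
    }
  }
  out <- as.data.frame(out)
  attr(out, "hemisphere") <- hemisphere
  out
}

#' Write a regional feature table in aparc.stats dialect
#'
#' Inverse of [read_aparc_stats()] up to numeric formatting; used by the
#' synthetic cohort generator so that generated fixtures exercise the same
#' parser as real FreeSurfer output.
#'
#' @param table Data frame as returned by [read_aparc_stats()]: 34 rows with
#'   StructName row names and the nine feature columns.
#' @param path Output file path.
#' @param hemisphere `"lh"` or `"rh"`, written into the header.
#' @return `path`, invisibly.
#' @export
write_aparc_stats <- function(table, path, hemisphere = c("lh", "rh")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(all(morph_features() %in% colnames(table)),
            all(dk_struct_names() %in% rownames(table)))
  table <- table[dk_struct_names(), morph_features()]
  header <- c(
    "# Table of FreeSurfer cortical parcellation anatomical statistics",
    sprintf("# hemi %s", hemisphere),
    "# anatomy_type surface",
    paste("# ColHeaders StructName",
          paste(morph_features(), collapse = " "))
  )
  rows <- sprintf(
    "%-28s %7d %9.1f %9.1f %7.3f %7.3f %8.3f %8.3f %5d %7.1f",
    rownames(table),
    as.integer(round(table$NumVert)), table$SurfArea, table$GrayVol,
    table$ThickAvg, table$ThickStd, table$MeanCurv, table$GausCurv,
    as.integer(round(table$FoldInd)), table$CurvInd
  )
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Assemble a 68-region subject feature matrix from two hemisphere tables
#'
#' Stacks the left- and right-hemisphere regional tables into the canonical
#' 68 x 9 subject feature matrix (left regions first, each hemisphere in
#' alphabetical StructName order).
#'
#' @param lh,rh Tables from [read_aparc_stats()] with `hemisphere`
#'   attributes `"lh"` and `"rh"` respectively.
#' @param subject_id,session_id Identifiers recorded as attributes on the
#'   result (used by the reliability machinery).
#' @return A 68 x 9 numeric matrix, rows named by region label, columns by
#'   feature, with attributes `subject_id` and `session_id`.
#' @export
assemble_subject_features <- function(lh, rh,
                                      subject_id = NA_character_,
                                      session_id = NA_integer_) {
  hl <- attr(lh, "hemisphere")
  hr <- attr(rh, "hemisphere")
  if (is.null(hl) || is.null(hr)) {
    stopf("hemisphere tables must carry a 'hemisphere' attribute")
  }
  if (identical(hl, hr)) {
    stopf("both tables are tagged '%s': need one lh and one rh table", hl)
  }
  if (!identical(hl, "lh") || !identical(hr, "rh")) {
    stopf("arguments must be (lh, rh), got ('%s', '%s')", hl, hr)
  }
  m <- rbind(as.matrix(lh[dk_struct_names(), morph_features()]),
             as.matrix(rh[dk_struct_names(), morph_features()]))
  rownames(m) <- dk_region_names()
  subject_features(m, subject_id = subject_id, session_id = session_id)
}

#' Construct a subject feature matrix from a plain matrix
#'
#' @param values Numeric 68 x F matrix with region row names in canonical
#'   order and feature column names.
#' @param subject_id,session_id Identifiers stored as attributes.
#' @return The validated matrix with identifier attributes.
#' @export
subject_features <- function(values, subject_id = NA_character_,
                             session_id = NA_integer_) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyNA(values)) stopf("subject feature matrix contains missing values")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("subject feature matrix needs region row names and feature column names")
  }
  attr(values, "subject_id") <- as.character(subject_id)
  attr(values, "session_id") <- as.integer(session_id)
  values
}

#' Split a subject feature matrix back into hemisphere tables
#'
#' Inverse of [assemble_subject_features()].
#'
#' @param mat 68 x F subject feature matrix.
#' @return List with elements `lh` and `rh`, each a data frame with
#'   StructName row names and a `hemisphere` attribute.
#' @export
split_hemispheres <- function(mat) {
  stopifnot(identical(rownames(mat), dk_region_names()))
  n <- length(dk_struct_names())
  out <- list(
    lh = as.data.frame(mat[seq_len(n), , drop = FALSE]),
    rh = as.data.frame(mat[n + seq_len(n), , drop = FALSE])
  )
  rownames(out$lh) <- dk_struct_names()
  rownames(out$rh) <- dk_struct_names()
  attr(out$lh, "hemisphere") <- "lh"
  attr(out$rh, "hemisphere") <- "rh"
  out
}
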