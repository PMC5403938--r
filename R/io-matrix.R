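# Labeled matrix TSV round-trip, cohort manifests, and BrainNet Viewer
# .node/.edge export.

#' Write a labeled symmetric matrix as TSV
#'
#' @param matrix Square symmetric numeric matrix with matching row/column
#'   labels.
#' @param path Output path.  The written file round-trips through
#'   [read_matrix()] with maximum absolute error below 1e-12.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  if (!is_symmetric_num(matrix)) {
    stopf("write_matrix() requires a square symmetric numeric matrix")
  }
  if (is.null(rownames(matrix))) {
    rownames(matrix) <- colnames(matrix) %||% paste0("n", seq_len(nrow(matrix)))
    colnames(matrix) <- rownames(matrix)
  }
  if (!identical(rownames(matrix), colnames(matrix))) {
    stopf("row and column labels must match")
  }
  fm <- format(matrix, digits = 17, trim = TRUE, scientific = TRUE)
  utils::write.table(fm, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a labeled matrix TSV written by [write_matrix()]
#'
#' @param path Input path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  as.matrix(tab)
}

#' Export a network for BrainNet Viewer
#'
#' Writes the `.node` (six whitespace-delimited columns: x, y, z, color,
#' size, label) and `.edge` (binary adjacency) files consumed by BrainNet
#' Viewer, e.g. to display hubs with node size proportional to betweenness
#' centrality.
#'
#' @param node_values Numeric vector of length 68 (node sizes, typically a
#'   BC vector), named by region or in canonical order.
#' @param net A [binary_network()]; its adjacency becomes the `.edge` file.
#' @param prefix Output path prefix; `<prefix>.node` and `<prefix>.edge` are
#'   written.
#' @param coords Data frame of region coordinates (default the packaged
#'   approximate centroids, [dk_centroids()]).
#' @param node_color Numeric vector of color codes (default all 1).
#' @param labels Node labels (default region labels).
#' @return Character vector of the two paths written, invisibly.
#' @export
export_brainnet <- function(node_values, net, prefix,
                            coords = dk_centroids(),
                            node_color = NULL, labels = NULL) {
  regions <- rownames(net$adjacency)
  n <- length(regions)
  if (length(node_values) != n) {
    stopf("need %d node values, got %d", n, length(node_values))
  }
  if (!is.null(names(node_values))) node_values <- node_values[regions]
  idx <- match(regions, coords$region)
  if (anyNA(idx)) {
    stopf("missing coordinates for region(s): %s",
          paste(regions[is.na(idx)], collapse = ", "))
  }
  node_color <- node_color %||% rep(1, n)
  labels <- labels %||% regions
  node_path <- paste0(prefix, ".node")
  edge_path <- paste0(prefix, ".edge")
  writeLines(sprintf("%g\t%g\t%g\t%g\t%.10g\t%s",
                     coords$x[idx], coords$y[idx], coords$z[idx],
                     node_color, node_values, labels),
             node_path)
  utils::write.table(net$adjacency, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(node_path, edge_path))
}

#' Read / write a cohort manifest
#'
#' A cohort manifest is a CSV with columns `subject_id`, `session_id`,
#' `lh_path`, `rh_path`, one row per subject-session, listing the two
#' hemisphere statistics files of each scan.  (subject, session) pairs must
#' be unique; test-retest analyses additionally require exactly the sessions
#' 1 and 2 for every subject (see [validate_test_retest()]).
#'
#' @param path CSV path.
#' @return Data frame manifest.
#' @export
read_cohort_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "session_id", "lh_path", "rh_path")
  if (!all(needed %in% colnames(man))) {
    stopf("manifest must have columns %s", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(man[, c("subject_id", "session_id")])) {
    stopf("duplicate (subject_id, session_id) pairs in manifest")
  }
  man
}

#' @rdname read_cohort_manifest
#' @param manifest Manifest data frame.
#' @export
write_cohort_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check that a manifest describes a complete two-session design
#'
#' @param manifest Manifest data frame.
#' @return `manifest`, invisibly; errors if any subject lacks exactly the
#'   sessions 1 and 2.
#' @export
validate_test_retest <- function(manifest) {
  bad <- vapply(split(manifest$session_id, manifest$subject_id),
                function(s) !setequal(s, c(1L, 2L)), logical(1))
  if (any(bad)) {
    stopf("subject(s) without exactly sessions 1 and 2: %s",
          paste(names(bad)[bad], collapse = ", "))
  }
  invisible(manifest)
}

#' Load all subject feature matrices listed in a manifest
#'
#' @param manifest Manifest data frame (see [read_cohort_manifest()]).
#' @param base_dir Optional directory that relative paths are resolved
#'   against.
#' @return List of 68 x 9 subject feature matrices (one per manifest row)
#'   with `subject_id` / `session_id` attributes.
#' @export
load_cohort <- function(manifest, base_dir = NULL) {
  resolve <- function(p) if (is.null(base_dir)) p else file.path(base_dir, p)
  lapply(seq_len(nrow(manifest)), function(i) {
    lh <- read_aparc_stats(resolve(manifest$lh_path[[i]]), "lh")
    rh <- read_aparc_stats(resolve(manifest$rh_path[[i]]), "rh")
    assemble_subject_features(lh, rh,
                              subject_id = manifest$subject_id[[i]],
                              session_id = manifest$session_id[[i]])
  })
}
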