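# Programmatic fixtures: a deterministic plausible hemisphere table and an
# aparc.stats writer with controllable defects.

fixture_hemi_table <- function(seed = 404, hemisphere = "lh") {
  cfg <- synth_config(n_subjects = 1L, n_sessions = 1L, seed = seed)
  m <- generate_cohort(cfg)$subjects[[1L]]
  split_hemispheres(m)[[hemisphere]]
}

# Writes an aparc.stats-dialect file from a table, optionally mangled.
write_fixture_aparc <- function(path, table = fixture_hemi_table(),
                                hemisphere = "lh",
                                drop_region = NULL,
                                permute_cols = FALSE,
                                extra_col = FALSE,
                                drop_col = NULL,
                                non_numeric_at = NULL) {
  tab <- table
  if (!is.null(drop_region)) tab <- tab[setdiff(rownames(tab), drop_region), ]
  cols <- morph_features()
  if (!is.null(drop_col)) cols <- setdiff(cols, drop_col)
  if (permute_cols) cols <- rev(cols)
  vals <- matrix(sprintf("%.6g", as.matrix(tab[, cols])), nrow = nrow(tab))
  if (!is.null(non_numeric_at)) {
    vals[non_numeric_at[[1L]], non_numeric_at[[2L]]] <- "oops"
  }
  header_cols <- c("StructName", cols)
  rows <- apply(cbind(rownames(tab), vals), 1L, paste, collapse = " ")
  if (extra_col) {
    header_cols <- c(header_cols, "ExtraMeasure")
    rows <- paste(rows, "0.5")
  }
  writeLines(c(
    "# Table of FreeSurfer cortical parcellation anatomical statistics",
    sprintf("# hemi %s", hemisphere),
    paste("# ColHeaders", paste(header_cols, collapse = " ")),
    rows
  ), path)
  invisible(path)
}

# small in-memory cohort for module-level tests
small_cohort <- function(n_subjects = 6L, seed = 99L, ...) {
  generate_cohort(synth_config(n_subjects = n_subjects, seed = seed, ...))
}
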