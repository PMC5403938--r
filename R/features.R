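# Feature standardization and test-retest feature screening.
#
# Because the nine morphometric features span several orders of magnitude
# (vertex counts in the thousands, Gaussian curvature around 1e-2), each
# feature is z-scored across the 68 regions of one subject/session before
# any correlation is computed.  Standardization is strictly within-subject:
# the construction is individual-based, and pooling across subjects would
# leak population information into a single-subject network.

#' Z-score feature columns across regions
#'
#' Standardizes each feature column of a subject feature matrix to mean 0
#' and sample standard deviation 1 (denominator n - 1) across its regions.
#' The operation is affine-invariant per column, so measurement units
#' cancel.
#'
#' @param matrix Subject feature matrix (regions x features).
#' @param pooled Optional list with elements `center` and `scale` (named per
#'   feature) to standardize against externally supplied moments instead of
#'   the within-subject ones; the default `NULL` uses within-subject
#'   moments.
#' @return Matrix of the same shape with standardized columns; subject and
#'   session attributes are preserved.
#' @export
zscore_features <- function(matrix, pooled = NULL) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (anyNA(matrix)) stopf("feature matrix contains missing values")
  if (is.null(pooled)) {
    ctr <- colMeans(matrix)
    scl <- apply(matrix, 2L, stats::sd)
  } else {
    ctr <- pooled$center[colnames(matrix)]
    scl <- pooled$scale[colnames(matrix)]
  }
  flat <- !is.finite(scl) | scl == 0
  if (any(flat)) {
    stopf("constant feature column(s), cannot standardize: %s",
          paste(colnames(matrix)[flat], collapse = ", "))
  }
  out <- sweep(sweep(matrix, 2L, ctr, "-"), 2L, scl, "/")
  attr(out, "subject_id") <- attr(matrix, "subject_id")
  attr(out, "session_id") <- attr(matrix, "session_id")
  attr(out, "standardized") <- TRUE
  out
}

#' Screen features for test-retest robustness
#'
#' For each candidate feature, takes the whole-brain mean (average over the
#' 68 regions) per subject and session and estimates its one-way
#' random-effects intraclass correlation across subjects.  Features whose
#' whole-brain mean is not reproducible between sessions are poor building
#' blocks for a test-retest-stable connectome.
#'
#' @param cohort List of subject feature matrices carrying `subject_id` and
#'   `session_id` attributes; every subject must appear with sessions 1
#'   and 2.
#' @return A `feature_screen` data frame with one row per feature: `feature`,
#'   `icc`, `f_statistic`, `p_value`.
#' @seealso [icc_oneway()], [select_features()]
#' @export
screen_feature_reliability <- function(cohort) {
  subj <- vapply(cohort, function(m) attr(m, "subject_id"), character(1))
  sess <- vapply(cohort, function(m) attr(m, "session_id"), integer(1))
  if (anyNA(subj) || anyNA(sess)) {
    stopf("cohort matrices must carry subject_id and session_id attributes")
  }
  bad <- vapply(split(sess, subj), function(s) !setequal(s, c(1L, 2L)),
                logical(1))
  if (any(bad)) {
    stopf("subject(s) missing a session: %s",
          paste(names(bad)[bad], collapse = ", "))
  }
  feats <- colnames(cohort[[1L]])
  subjects <- sort(unique(subj))
  res <- lapply(feats, function(f) {
    wb <- vapply(cohort, function(m) mean(m[, f]), numeric(1))
    tab <- matrix(NA_real_, nrow = length(subjects), ncol = 2L,
                  dimnames = list(subjects, c("1", "2")))
    tab[cbind(match(subj, subjects), sess)] <- wb
    icc <- icc_oneway(tab)
    data.frame(feature = f, icc = icc$icc, f_statistic = icc$f_statistic,
               p_value = icc$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("feature_screen", class(out))
  out
}

#' Select reproducible features from a screen
#'
#' Keeps the features whose ICC significance test passes `p_value < p_max`
#' (and, optionally, whose ICC estimate reaches `icc_min`).  The default
#' `p_max = 0.1` reproduces the canonical 9-to-7 reduction on the reference
#' screen of [oasis_reference_screen()]: mean thickness (p = 0.053) and
#' Gaussian curvature (p = 0.076) survive, fold index (p = 0.76) and
#' curvature index (p = 0.29) are dropped.  No principled universal
#' threshold exists, hence both knobs are exposed.
#'
#' @param screen A `feature_screen` data frame.
#' @param p_max Significance threshold on the ICC F-test p-value.
#' @param icc_min Optional lower bound on the ICC estimate (default none).
#' @return Character vector of selected feature names.
#' @export
select_features <- function(screen, p_max = 0.1, icc_min = -Inf) {
  stopifnot(all(c("feature", "icc", "p_value") %in% colnames(screen)))
  sel <- screen$feature[screen$p_value < p_max & screen$icc >= icc_min]
  if (length(sel) == 0L) {
    stopf(paste("no feature passes the screen (p_max = %g, icc_min = %g);",
                "supply a feature subset manually"), p_max, icc_min)
  }
  sel
}

#' Reference feature screen from a 55-subject OASIS test-retest cohort
#'
#' Whole-brain-mean ICC estimates and p-values for the nine morphometric
#' features as reported for a healthy 55-subject OASIS cohort scanned twice
#' (FreeSurfer 5.3.0 processing).  Shipped so that the default feature
#' selection rule can be exercised without imaging data.
#'
#' @return A `feature_screen` data frame with 9 rows.
#' @export
oasis_reference_screen <- function() {
  out <- data.frame(
    feature = c("NumVert", "SurfArea", "GrayVol", "ThickAvg", "ThickStd",
                "MeanCurv", "GausCurv", "FoldInd", "CurvInd"),
    icc     = c(0.95, 0.99, 0.96, 0.73, 0.94, 0.80, 0.68, 0.73, 0.36),
    p_value = c(3.1e-4, 7.3e-6, 1.6e-4, 5.3e-2, 6.3e-4,
                2.4e-2, 7.6e-2, 0.76, 0.29),
    stringsAsFactors = FALSE
  )
  class(out) <- c("feature_screen", class(out))
  out
}
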