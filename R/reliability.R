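# Test-retest reliability: one-way random-effects intraclass correlation.
#
# ICC is the between-subject share of the total variance,
# sigma2_between / (sigma2_between + sigma2_within), estimated from the
# one-way ANOVA decomposition.  The one-way model (no session effect)
# matches the variance-ratio definition; two-way forms differ only in how
# a systematic session shift is handled and are out of scope here.

#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' One-way ANOVA decomposition of an n-subjects by k-sessions measurement
#' table: `MSB` between subjects, `MSW` within; the consistency estimator
#' is `ICC(1,1) = (MSB - MSW) / (MSB + (k - 1) MSW)`, equivalent to the
#' variance-component form with `sigma2_within = MSW` and
#' `sigma2_between = (MSB - MSW) / k`.  Negative component estimates are
#' floored at zero for the reported ICC; the raw (possibly negative) value
#' is also returned.  Significance is the F-test `MSB / MSW` with
#' `(n - 1, n (k - 1))` degrees of freedom.
#'
#' @param measurements Numeric matrix, subjects in rows, sessions in
#'   columns; complete, n >= 3, k >= 2.
#' @return Object of class `icc_result`: list with `icc`, `icc_raw`,
#'   `sigma2_between`, `sigma2_within`, `msb`, `msw`, `f_statistic`, `df1`,
#'   `df2`, `p_value`, `n`, `k`.
#' @examples
#' m <- cbind(s1 = c(1, 2, 3, 5), s2 = c(2, 1, 3, 4))
#' icc_oneway(m)$icc
#' @export
icc_oneway <- function(measurements) {
  m <- as.matrix(measurements)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3L) stopf("need at least 3 subjects, got %d", n)
  if (k < 2L) stopf("need at least 2 sessions, got %d", k)
  if (anyNA(m)) stopf("measurement table has missing cells")
  if (max(m) == min(m)) stopf("all measurements identical; total variance is zero")
  grand <- mean(m)
  row_means <- rowMeans(m)
  ssb <- k * sum((row_means - grand)^2)
  ssw <- sum((m - row_means)^2)
  df1 <- n - 1L
  df2 <- n * (k - 1L)
  msb <- ssb / df1
  msw <- ssw / df2
  if (msw == 0) {
    icc <- icc_raw <- 1
    f <- Inf
    p <- 0
    s2b <- msb / k
  } else {
    icc_raw <- (msb - msw) / (msb + (k - 1) * msw)
    s2b <- max((msb - msw) / k, 0)
    icc <- s2b / (s2b + msw)
    f <- msb / msw
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(
    list(icc = icc, icc_raw = icc_raw,
         sigma2_between = s2b, sigma2_within = msw,
         msb = msb, msw = msw,
         f_statistic = f, df1 = df1, df2 = df2, p_value = p,
         n = n, k = k),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "<icc> ICC(1,1) = %.3f (%s)  F(%d,%d) = %.3g, p = %.3g  [n %d, k %d]\n",
    x$icc, classify_reliability(x$icc), x$df1, x$df2, x$f_statistic,
    x$p_value, x$n, x$k))
  invisible(x)
}

#' Qualitative reliability label
#'
#' `> 0.75` is "excellent", `0.6` to `0.75` (inclusive) "good", anything
#' lower "below-good".
#'
#' @param icc Numeric vector of ICC values.
#' @return Character vector of labels.
#' @export
classify_reliability <- function(icc) {
  stopifnot(all(is.finite(icc)))
  ifelse(icc > 0.75, "excellent",
         ifelse(icc >= 0.6, "good", "below-good"))
}

#' Per-sparsity test-retest reliability of a network metric
#'
#' Given a long table of per-subject, per-session metric values along a
#' sparsity sweep (two sessions per subject, identical processing), fits
#' [icc_oneway()] at each sparsity and reports the sweep-mean ICC.
#'
#' @param metrics Data frame with columns `subject`, `session` (1/2),
#'   `sparsity` and `value`.
#' @return Data frame with one row per sparsity (`sparsity`, `icc`,
#'   `f_statistic`, `p_value`, `label`) and attribute `mean_icc`.
#' @export
metric_reliability <- function(metrics) {
  needed <- c("subject", "session", "sparsity", "value")
  stopifnot(all(needed %in% colnames(metrics)))
  rows <- lapply(split(metrics, metrics$sparsity), function(d) {
    wide <- tapply(d$value, list(d$subject, d$session), identity)
    if (anyNA(wide)) {
      stopf("incomplete sessions at sparsity %s", d$sparsity[[1L]])
    }
    icc <- icc_oneway(wide)
    data.frame(sparsity = d$sparsity[[1L]], icc = icc$icc,
               f_statistic = icc$f_statistic, p_value = icc$p_value,
               label = classify_reliability(icc$icc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sparsity), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mean_icc") <- mean(out$icc)
  out
}

#' Per-sparsity reliability of nodal betweenness
#'
#' Nodal BC admits two test-retest summaries per sparsity, both reported
#' because the aggregation convention is ambiguous: `icc_node_mean` is the
#' ICC of each subject's node-mean BC, and `icc_mean_node` is the mean over
#' nodes of per-node ICCs (nodes whose BC is identical across all subjects
#' and sessions are skipped in the mean).
#'
#' @param bc_session1,bc_session2 3-d arrays subjects x sparsities x nodes
#'   with identical dimensions, one per session.
#' @return Data frame with one row per sparsity: `sparsity`,
#'   `icc_node_mean`, `icc_mean_node`.
#' @export
bc_reliability <- function(bc_session1, bc_session2) {
  stopifnot(identical(dim(bc_session1), dim(bc_session2)))
  spars <- dimnames(bc_session1)[[2L]]
  rows <- lapply(seq_along(spars), function(j) {
    b1 <- bc_session1[, j, ]
    b2 <- bc_session2[, j, ]
    icc_nm <- icc_oneway(cbind(rowMeans(b1), rowMeans(b2)))$icc
    per_node <- vapply(seq_len(ncol(b1)), function(v) {
      tab <- cbind(b1[, v], b2[, v])
      if (max(tab) == min(tab)) NA_real_ else icc_oneway(tab)$icc
    }, numeric(1))
    data.frame(sparsity = as.numeric(spars[[j]]),
               icc_node_mean = icc_nm,
               icc_mean_node = mean(per_node, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
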