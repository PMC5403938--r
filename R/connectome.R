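# Individual connectome construction: Pearson correlation of per-region
# feature vectors, absolute value, and top-k binarization over a sparsity
# sweep.
#
# Sparsity s is the fraction of realized edges among the N(N-1)/2 possible
# undirected pairs (2278 for N = 68).  The edge count is k = round(s * 2278)
# with half rounded away from zero, and the k strongest |r| pairs are kept
# under a fixed total order (|r| descending, then (i, j) lexicographic
# ascending on ties).  The fixed order makes edge sets nested across the
# sweep and the result invariant to positive rescaling of |r|.

#' Feature-vector correlation matrix
#'
#' Computes the Pearson correlation between every pair of regions' F-long
#' standardized feature vectors: the individual morphological connectivity
#' matrix.
#'
#' @param std Standardized subject feature matrix (regions x features), as
#'   produced by [zscore_features()]; at least 3 feature columns.
#' @return Symmetric regions x regions correlation matrix with unit
#'   diagonal, attribute `absolute = FALSE`, and subject/session attributes
#'   carried over.
#' @export
feature_correlation_matrix <- function(std) {
  stopifnot(is.matrix(std), is.numeric(std))
  if (ncol(std) < 3L) {
    stopf("need at least 3 features to correlate feature vectors, got %d",
          ncol(std))
  }
  row_sd <- apply(std, 1L, stats::sd)
  flat <- !is.finite(row_sd) | row_sd == 0
  if (any(flat)) {
    stopf("constant feature vector for region(s): %s",
          paste(rownames(std)[flat], collapse = ", "))
  }
  r <- stats::cor(t(std))
  diag(r) <- 1
  attr(r, "absolute") <- FALSE
  attr(r, "subject_id") <- attr(std, "subject_id")
  attr(r, "session_id") <- attr(std, "session_id")
  attr(r, "features") <- colnames(std)
  r
}

#' Absolute-value connectivity matrix
#'
#' Takes the element-wise absolute value so that strong negative
#' correlations are retained alongside strong positive ones before
#' binarization.
#'
#' @param connectivity Correlation matrix from
#'   [feature_correlation_matrix()].
#' @return Matrix of |r| values with attribute `absolute = TRUE`.
#' @export
absolute_matrix <- function(connectivity) {
  if (isTRUE(attr(connectivity, "absolute"))) {
    stopf("matrix is already in absolute form")
  }
  out <- abs(connectivity)
  attributes(out) <- attributes(connectivity)
  attr(out, "absolute") <- TRUE
  out
}

#' Edge count at a given sparsity
#'
#' @param s Sparsity fraction in (0, 1].
#' @param n_regions Number of nodes (default 68, giving 2278 pairs).
#' @return Integer edge count `round(s * n(n-1)/2)`, half away from zero.
#' @export
sparsity_edge_count <- function(s, n_regions = 68L) {
  as.integer(round_half_up(s * n_regions * (n_regions - 1) / 2))
}

#' Binary undirected network
#'
#' Container for an unweighted undirected graph: a symmetric 0/1 adjacency
#' matrix with zero diagonal, plus the sparsity it was thresholded at.
#'
#' @param adjacency Symmetric 0/1 numeric matrix, zero diagonal.
#' @param sparsity Sparsity fraction (optional; `NA` for ad-hoc graphs).
#' @return Object of class `binary_network`: list with `adjacency`,
#'   `sparsity`, `k` (edge count) and `n` (node count).
#' @export
binary_network <- function(adjacency, sparsity = NA_real_) {
  stopifnot(is.matrix(adjacency))
  storage.mode(adjacency) <- "double"
  if (!is_symmetric_num(adjacency, tol = 0)) {
    stopf("adjacency must be square and exactly symmetric")
  }
  if (any(diag(adjacency) != 0)) stopf("self-loops are not allowed")
  if (!all(adjacency %in% c(0, 1))) stopf("adjacency must be 0/1")
  if (is.null(rownames(adjacency))) {
    rownames(adjacency) <- paste0("n", seq_len(nrow(adjacency)))
    colnames(adjacency) <- rownames(adjacency)
  }
  structure(
    list(adjacency = adjacency, sparsity = sparsity,
         k = as.integer(sum(adjacency) / 2), n = nrow(adjacency)),
    class = "binary_network"
  )
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (sparsity %s)\n",
              x$n, x$k,
              if (is.na(x$sparsity)) "unset" else sprintf("%.3f", x$sparsity)))
  invisible(x)
}

# fixed total order on the upper-triangle pairs of an absolute matrix:
# weight descending, then (i, j) lexicographic ascending
.ranked_pairs <- function(absmat) {
  iu <- which(upper.tri(absmat))
  ri <- row(absmat)[iu]
  ci <- col(absmat)[iu]
  w <- absmat[iu]
  ord <- order(-w, ri, ci)
  list(i = ri[ord], j = ci[ord], w = w[ord])
}

#' Binarize an absolute connectivity matrix at a target sparsity
#'
#' Keeps the `k = round(s * n(n-1)/2)` strongest off-diagonal pairs (ties
#' broken lexicographically) and returns the unweighted undirected network.
#'
#' @param connectivity Absolute connectivity matrix (see
#'   [absolute_matrix()]).
#' @param s Sparsity fraction in (0, 1].
#' @return A [binary_network()].
#' @export
binarize_at_sparsity <- function(connectivity, s) {
  if (!isTRUE(attr(connectivity, "absolute"))) {
    stopf("binarization requires the absolute matrix; call absolute_matrix() first")
  }
  n <- nrow(connectivity)
  n_pairs <- n * (n - 1) / 2
  if (s <= 0 || s > 1) stopf("sparsity must be in (0, 1], got %g", s)
  k <- sparsity_edge_count(s, n)
  if (k < 1L) stopf("sparsity %g yields zero edges on %d nodes", s, n)
  k <- min(k, as.integer(n_pairs))
  rp <- .ranked_pairs(connectivity)
  adj <- matrix(0, n, n, dimnames = dimnames(connectivity))
  sel <- seq_len(k)
  adj[cbind(rp$i[sel], rp$j[sel])] <- 1
  adj[cbind(rp$j[sel], rp$i[sel])] <- 1
  binary_network(adj, sparsity = s)
}

#' Threshold a connectivity matrix over a sparsity sweep
#'
#' Produces one binary network per sparsity value.  Because the pair order
#' is fixed, edge sets are nested along the sweep.  If the sparsest network
#' leaves isolated nodes, a warning is emitted (the sweep minimum is meant
#' to guarantee none).
#'
#' @param connectivity Absolute connectivity matrix.
#' @param s_min,s_max,step Sweep definition; defaults 0.20 to 0.40 in steps
#'   of 0.01 (21 networks).
#' @param warn_isolated Warn if isolated nodes remain at `s_min`.
#' @return Named list of [binary_network()] objects (names are the sparsity
#'   values formatted `"%.2f"`).
#' @export
sparsity_sweep <- function(connectivity, s_min = 0.20, s_max = 0.40,
                           step = 0.01, warn_isolated = TRUE) {
  if (s_min > s_max) stopf("s_min must not exceed s_max")
  s_values <- if (s_min + step > s_max + 1e-12) {
    s_min
  } else {
    seq(s_min, s_max + 1e-12, by = step)
  }
  nets <- lapply(s_values, function(s) binarize_at_sparsity(connectivity, s))
  names(nets) <- sprintf("%.2f", s_values)
  if (warn_isolated) {
    iso <- check_no_isolated_nodes(nets[[1L]])
    if (length(iso) > 0L) {
      warning(sprintf("isolated node(s) at sparsity %.2f: %s",
                      s_values[[1L]], paste(iso, collapse = ", ")),
              call. = FALSE)
    }
  }
  nets
}

#' List isolated (degree-zero) nodes of a network
#'
#' @param net A [binary_network()].
#' @return Character vector of isolated node labels (empty if none).
#' @export
check_no_isolated_nodes <- function(net) {
  deg <- rowSums(net$adjacency)
  names(deg)[deg == 0]
}

#' Edge list of a binary network
#'
#' @param net A [binary_network()].
#' @param weights Optional symmetric matrix (e.g. the |r| matrix) to attach
#'   a weight column.
#' @return Data frame with columns `region_i`, `region_j` and optionally
#'   `weight`, one row per undirected edge.
#' @export
edge_list <- function(net, weights = NULL) {
  adj <- net$adjacency
  iu <- which(upper.tri(adj) & adj == 1)
  out <- data.frame(
    region_i = rownames(adj)[row(adj)[iu]],
    region_j = colnames(adj)[col(adj)[iu]],
    stringsAsFactors = FALSE
  )
  if (!is.null(weights)) out$weight <- weights[iu]
  out
}
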