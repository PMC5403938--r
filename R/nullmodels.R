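# Matched random networks and small-world configurations.
#
# The null ensemble preserves node count, edge count and the full degree
# sequence via double-edge-swap (Maslov-Sneppen) rewiring, the standard
# convention for "random networks with the same number of nodes and edges"
# in the brain-network literature; a pure Erdos-Renyi option (same N and k
# only) is available.

#' Matched random network
#'
#' @param net A [binary_network()] with at least 2 edges.
#' @param n_swaps Number of attempted double-edge swaps (default `10 * k`).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param method `"degree"` for degree-preserving rewiring (default) or
#'   `"er"` for an Erdos-Renyi graph with the same node and edge counts.
#' @return A [binary_network()] with the same sparsity annotation.
#' @export
random_network <- function(net, n_swaps = 10L * net$k, seed = NULL,
                           method = c("degree", "er")) {
  method <- match.arg(method)
  if (net$k < 2L) stopf("need at least 2 edges to randomize")
  adj <- with_seed(seed, {
    if (method == "degree") {
      g <- as_igraph(net)
      rg <- igraph::rewire(
        g, igraph::keeping_degseq(loops = FALSE, niter = n_swaps))
      igraph::as_adjacency_matrix(rg, sparse = FALSE)
    } else {
      rg <- igraph::sample_gnm(net$n, net$k)
      igraph::as_adjacency_matrix(rg, sparse = FALSE)
    }
  })
  dimnames(adj) <- dimnames(net$adjacency)
  out <- binary_network(adj, sparsity = net$sparsity)
  if (method == "degree" && identical(out$adjacency, net$adjacency) &&
      net$n > 3L) {
    warning("rewiring left the network unchanged (rigid graph or too few swaps)",
            call. = FALSE)
  }
  out
}

#' Small-world configurations against a matched null ensemble
#'
#' Computes gamma = Cp / mean(Cp_null), lambda = Lp / mean(Lp_null) and
#' sigma = gamma / lambda over `n_null` independent matched random
#' networks.  sigma > 1 (high normalized clustering at near-random path
#' length) is the usual one-number small-worldness criterion.
#'
#' @param net A [binary_network()] (connected enough for Lp).
#' @param n_null Number of null realizations (default 100).
#' @param seed Optional seed governing the whole ensemble.
#' @param n_swaps Swap budget per realization (default `10 * k`).
#' @param method Null model, see [random_network()].
#' @return Object of class `small_world_result`: list with `cp`, `lp`,
#'   `cp_rand`, `lp_rand` (null means), `cp_rand_sd`, `lp_rand_sd`,
#'   `gamma`, `lambda`, `sigma`, `n_null`, `seed`.
#' @export
small_world <- function(net, n_null = 100L, seed = NULL,
                        n_swaps = 10L * net$k, method = c("degree", "er")) {
  method <- match.arg(method)
  cp <- clustering(net)$cp
  lp <- characteristic_path_length(net)
  null_stats <- with_seed(seed, {
    vapply(seq_len(n_null), function(b) {
      rn <- suppressWarnings(
        random_network(net, n_swaps = n_swaps, method = method))
      c(clustering(rn)$cp, characteristic_path_length(rn))
    }, numeric(2))
  })
  cp_rand <- mean(null_stats[1L, ])
  lp_rand <- mean(null_stats[2L, ])
  if (cp_rand == 0) stopf("null clustering is zero; gamma undefined")
  gamma <- cp / cp_rand
  lambda <- lp / lp_rand
  structure(
    list(cp = cp, lp = lp, cp_rand = cp_rand, lp_rand = lp_rand,
         cp_rand_sd = stats::sd(null_stats[1L, ]),
         lp_rand_sd = stats::sd(null_stats[2L, ]),
         gamma = gamma, lambda = lambda, sigma = gamma / lambda,
         n_null = n_null, seed = seed),
    class = "small_world_result"
  )
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf(
    "<small_world> Cp %.3f (null %.3f)  Lp %.3f (null %.3f)\n  gamma %.3f  lambda %.3f  sigma %.3f  [n_null %d]\n",
    x$cp, x$cp_rand, x$lp, x$lp_rand, x$gamma, x$lambda, x$sigma, x$n_null))
  invisible(x)
}

#' Independent two-sample t-test between real and null metric samples
#'
#' Classical pooled-variance (equal-variance) two-sample t-test, two-sided,
#' as used to compare subjects' network metrics with their matched-null
#' counterparts at each sparsity.
#'
#' @param real,null Numeric vectors (>= 2 values each).
#' @return List with `t`, `df`, `p`.
#' @export
compare_real_vs_null <- function(real, null) {
  if (length(real) < 2L || length(null) < 2L) {
    stopf("both samples need at least 2 observations")
  }
  if (stats::var(real) + stats::var(null) == 0) {
    if (mean(real) == mean(null)) {
      return(list(t = 0, df = length(real) + length(null) - 2L, p = 1))
    }
    stopf("zero pooled variance with unequal means; t undefined")
  }
  ht <- stats::t.test(real, null, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR control at level `q`: p-values are BH-adjusted and rejected
#' where the adjusted value is at most `q`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param q Target false discovery rate (default 0.05).
#' @return Data frame with columns `p`, `p_adjusted`, `reject`.
#' @export
fdr_correct <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0L) stopf("empty p-value list")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE) || anyNA(pvalues)) {
    stopf("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, p_adjusted = adj, reject = adj <= q)
}

#' Real-versus-null comparison across a sparsity sweep
#'
#' Runs [compare_real_vs_null()] per sparsity and FDR-corrects the p-values
#' across the sweep.
#'
#' @param real,null Matrices subjects x sparsities of a metric (e.g. Cp) for
#'   real networks and per-subject null means; identical column sets.
#' @param q FDR level.
#' @return Data frame with one row per sparsity: `sparsity`, `t`, `df`,
#'   `p`, `p_adjusted`, `reject`.
#' @export
compare_sweep <- function(real, null, q = 0.05) {
  stopifnot(identical(colnames(real), colnames(null)))
  rows <- lapply(colnames(real), function(s) {
    cmp <- compare_real_vs_null(real[, s], null[, s])
    data.frame(sparsity = as.numeric(s), t = cmp$t, df = cmp$df, p = cmp$p)
  })
  out <- do.call(rbind, rows)
  fdr <- fdr_correct(out$p, q = q)
  out$p_adjusted <- fdr$p_adjusted
  out$reject <- fdr$reject
  out
}
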