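# Nodal and global graph measures on binary undirected networks.
#
# Conventions:
#  * Ci = 2 * E_i / (k_i * (k_i - 1)) with Ci = 0 for degree < 2;
#    Cp is the unweighted mean of Ci over all nodes.
#  * Lp uses Newman's harmonic-mean form, the inverse of the mean inverse
#    shortest-path distance over ordered pairs, so disconnected pairs
#    contribute zero instead of making Lp infinite.
#  * Betweenness is Freeman's unnormalized count with each unordered pair
#    {s, t} counted once, so hub magnitudes are on the familiar scale for
#    68-node networks (tens to low hundreds).
#
# Shortest-path machinery is delegated to igraph; the test suite checks all
# three measures against independent brute-force oracles.

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Clustering coefficients
#'
#' Per-node clustering coefficient Ci (the fraction of a node's neighbor
#' pairs that are themselves connected; 0 for nodes of degree < 2) and
#' their unweighted mean Cp.
#'
#' @param net A [binary_network()].
#' @return List with `ci` (named numeric vector) and `cp` (scalar).
#' @export
clustering <- function(net) {
  g <- as_igraph(net)
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(ci) <- rownames(net$adjacency)
  list(ci = ci, cp = mean(ci))
}

#' Characteristic path length (harmonic-mean form)
#'
#' `Lp = [ (1 / (N (N - 1))) * sum_{i != j} 1 / d(i, j) ]^-1`, where d is
#' the unweighted shortest-path hop count and disconnected pairs contribute
#' `1 / d = 0`.  Finite for any network with at least one edge.
#'
#' @param net A [binary_network()].
#' @return Scalar Lp (>= 1).
#' @export
characteristic_path_length <- function(net) {
  if (net$k == 0L) stopf("Lp is undefined for a network with no edges")
  d <- igraph::distances(as_igraph(net))
  inv <- 1 / d          # Inf distances -> 0 contribution
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  n <- net$n
  1 / (sum(inv) / (n * (n - 1)))
}

#' Betweenness centrality
#'
#' Freeman betweenness: for each node v, the sum over unordered pairs
#' {s, t} (s, t != v) of the fraction of shortest s-t paths passing through
#' v.  Unnormalized by default; `normalized = TRUE` divides by
#' `(N - 1)(N - 2) / 2`.
#'
#' @param net A [binary_network()].
#' @param normalized Logical.
#' @return Named numeric vector of length N.
#' @export
betweenness_centrality <- function(net, normalized = FALSE) {
  bc <- igraph::betweenness(as_igraph(net), directed = FALSE,
                            normalized = normalized)
  names(bc) <- rownames(net$adjacency)
  bc
}

#' Node degrees
#'
#' @param net A [binary_network()].
#' @return Named integer vector of row sums of the adjacency; satisfies the
#'   handshake identity `sum(degree) == 2 * k`.
#' @export
node_degree <- function(net) {
  deg <- rowSums(net$adjacency)
  storage.mode(deg) <- "integer"
  deg
}

#' Global metrics of one network
#'
#' @param net A [binary_network()].
#' @return One-row data frame with `sparsity`, `k`, `cp`, `lp`.
#' @export
global_metrics <- function(net) {
  data.frame(sparsity = net$sparsity, k = net$k,
             cp = clustering(net)$cp,
             lp = characteristic_path_length(net))
}

#' Metrics across a sparsity sweep
#'
#' @param networks Named list of [binary_network()] objects from
#'   [sparsity_sweep()].
#' @return List with `global` (data frame, one row per sparsity: `sparsity`,
#'   `k`, `cp`, `lp`) and `bc` (matrix sparsities x nodes of betweenness
#'   values).
#' @export
sweep_metrics <- function(networks) {
  global <- do.call(rbind, lapply(networks, global_metrics))
  rownames(global) <- NULL
  bc <- do.call(rbind, lapply(networks, betweenness_centrality))
  rownames(bc) <- names(networks)
  list(global = global, bc = bc)
}
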