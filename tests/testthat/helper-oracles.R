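# Brute-force reference implementations, deliberately naive and independent
# of the package's igraph-backed code paths.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b && adj[nb[a], nb[b]] == 1) e <- e + 1
      }
    }
    ci[v] <- 2 * e / (k * (k - 1))
  }
  ci
}

oracle_lp <- function(adj) {
  d <- oracle_distances(adj)
  n <- nrow(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  1 / (sum(inv) / (n * (n - 1)))
}

# Betweenness by explicit shortest-path counting: N[s, v] is the number of
# shortest s-v paths (dynamic programme over BFS levels); a node v lies on
# a shortest s-t path iff d(s,v) + d(v,t) = d(s,t), contributing
# N[s,v] * N[t,v] / N[s,t].
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  np <- matrix(0, n, n)
  for (s in seq_len(n)) {
    np[s, s] <- 1
    finite <- which(is.finite(d[s, ]))
    for (v in finite[order(d[s, finite])]) {
      if (v == s) next
      pred <- which(adj[, v] == 1 & d[s, ] == d[s, v] - 1)
      np[s, v] <- sum(np[s, pred])
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      if (!is.finite(d[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          bc[v] <- bc[v] + np[s, v] * np[t, v] / np[s, t]
        }
      }
    }
  }
  bc
}

random_adj <- function(n, p) {
  a <- matrix(0, n, n)
  iu <- which(upper.tri(a))
  a[iu] <- as.numeric(stats::runif(length(iu)) < p)
  a + t(a)
}

make_net <- function(adj, sparsity = NA_real_) {
  binary_network(adj, sparsity = sparsity)
}

# all 2^(n(n-1)/2) undirected graphs on n nodes (use only for tiny n)
all_graphs <- function(n) {
  npairs <- n * (n - 1) / 2
  lapply(seq_len(2^npairs) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(npairs)]
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- bits
    a + t(a)
  })
}
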