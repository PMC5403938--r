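test_that("clustering matches hand-worked and brute-force values", {
  k4 <- matrix(1, 4, 4) - diag(4)
  cl <- clustering(make_net(k4))
  expect_equal(unname(cl$ci), rep(1, 4))
  expect_equal(cl$cp, 1)

  # triangle {1,2,3} plus pendant 4-1: C = (1/3, 1, 1, 0), Cp = 7/12
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[1, 3] <- a[2, 3] <- a[1, 4] <- 1
  a <- pmax(a, t(a))
  cl <- clustering(make_net(a))
  expect_equal(unname(cl$ci), c(1 / 3, 1, 1, 0))
  expect_equal(cl$cp, 7 / 12)

  set.seed(51)
  for (rep in 1:20) {
    adj <- random_adj(30, runif(1, 0.1, 0.5))
    expect_equal(unname(clustering(make_net(adj))$ci),
                 oracle_clustering(adj))
  }
})

test_that("harmonic-mean path length matches worked values and the oracle", {
  k5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(characteristic_path_length(make_net(k5)), 1)

  # path graph 1-2-3-4
  p4 <- matrix(0, 4, 4)
  p4[1, 2] <- p4[2, 3] <- p4[3, 4] <- 1
  p4 <- pmax(p4, t(p4))
  expect_equal(characteristic_path_length(make_net(p4)), 18 / 13)

  # two disjoint dyads: disconnected pairs contribute zero
  two_k2 <- matrix(0, 4, 4)
  two_k2[1, 2] <- two_k2[3, 4] <- 1
  two_k2 <- pmax(two_k2, t(two_k2))
  expect_equal(characteristic_path_length(make_net(two_k2)), 3)

  expect_error(characteristic_path_length(make_net(matrix(0, 3, 3))),
               "no edges")

  set.seed(52)
  for (rep in 1:15) {
    adj <- random_adj(25, runif(1, 0.05, 0.4))
    if (sum(adj) == 0) next
    expect_equal(characteristic_path_length(make_net(adj)), oracle_lp(adj))
  }
})

test_that("adding an edge never increases Lp", {
  set.seed(53)
  for (rep in 1:10) {
    adj <- random_adj(20, 0.15)
    if (sum(adj) == 0) next
    lp0 <- characteristic_path_length(make_net(adj))
    free <- which(upper.tri(adj) & adj == 0)
    pick <- sample(free, 1)
    adj2 <- adj
    adj2[pick] <- 1
    adj2[cbind(col(adj)[pick], row(adj)[pick])] <- 1
    expect_lte(characteristic_path_length(make_net(adj2)), lp0 + 1e-12)
  }
})

test_that("betweenness matches worked values and exhaustive path counting", {
  # 5-node star: C(4,2) = 6 leaf pairs all route through the center
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- 1
  star <- pmax(star, t(star))
  bc <- betweenness_centrality(make_net(star))
  expect_equal(unname(bc), c(6, 0, 0, 0, 0))

  k6 <- matrix(1, 6, 6) - diag(6)
  expect_equal(unname(betweenness_centrality(make_net(k6))), rep(0, 6))

  set.seed(54)
  for (rep in 1:12) {
    adj <- random_adj(25, runif(1, 0.08, 0.3))
    expect_equal(unname(betweenness_centrality(make_net(adj))),
                 oracle_betweenness(adj), tolerance = 1e-10)
  }
})

test_that("degree satisfies the handshake identity", {
  k5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(unname(node_degree(make_net(k5))), rep(4L, 5))
  expect_equal(unname(node_degree(make_net(matrix(0, 4, 4)))), rep(0L, 4))

  set.seed(55)
  net <- make_net(random_adj(40, 0.2))
  expect_equal(sum(node_degree(net)), 2L * net$k)
})

test_that("all metrics are equivariant under node relabeling", {
  set.seed(56)
  adj <- random_adj(20, 0.25)
  dimnames(adj) <- list(paste0("v", 1:20), paste0("v", 1:20))
  perm <- sample(20)
  padj <- adj[perm, perm]
  net <- make_net(adj)
  pnet <- make_net(padj)
  expect_equal(unname(clustering(pnet)$ci), unname(clustering(net)$ci[perm]))
  expect_equal(characteristic_path_length(pnet),
               characteristic_path_length(net))
  expect_equal(unname(betweenness_centrality(pnet)),
               unname(betweenness_centrality(net)[perm]))
  expect_equal(unname(node_degree(pnet)), unname(node_degree(net)[perm]))
})
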