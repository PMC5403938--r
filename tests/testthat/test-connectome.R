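test_that("feature-vector correlation matches the textbook formula", {
  z <- matrix(c(1, 0, -1,
                -1, 0, 1,
                1, 0, -1), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("f1", "f2", "f3")))
  r <- feature_correlation_matrix(z)
  expect_equal(r["a", "b"], -1)
  expect_equal(r["a", "c"], 1)
  expect_true(is_matrix_symmetric <- isTRUE(all.equal(r, t(r))))

  # element-wise oracle on a random 6 x 7 matrix
  set.seed(8)
  m <- matrix(rnorm(42), 6, 7,
              dimnames = list(paste0("r", 1:6), paste0("f", 1:7)))
  r <- feature_correlation_matrix(m)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      x <- m[i, ]; y <- m[j, ]
      oracle <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(r[i, j], oracle)
    }
  }
  expect_true(all(abs(r) <= 1 + 1e-12))

  flat <- m
  flat[2, ] <- 4
  expect_error(feature_correlation_matrix(flat), "r2")
  expect_error(feature_correlation_matrix(m[, 1:2]), "at least 3")
})

test_that("absolute_matrix folds signs exactly once", {
  set.seed(9)
  m <- matrix(rnorm(25), 5, 5)
  r <- feature_correlation_matrix(m)
  a <- absolute_matrix(r)
  expect_true(all(a >= 0))
  expect_equal(a[r < 0], -r[r < 0])
  expect_error(absolute_matrix(a), "already")

  pos <- abs(r)
  attr(pos, "absolute") <- FALSE
  expect_equal(unclass(absolute_matrix(pos)), unclass(pos),
               ignore_attr = TRUE)
})

test_that("binarization keeps exactly the k strongest pairs", {
  # toy 4-node |r| with upper triangle .9 .8 .7 .6 .5 .4; k = 2 at s = 1/3
  a <- matrix(0, 4, 4)
  a[upper.tri(a)] <- c(.9, .8, .6, .7, .5, .4)  # column-major fill
  a <- a + t(a)
  diag(a) <- 1
  attr(a, "absolute") <- TRUE
  net <- binarize_at_sparsity(a, 1 / 3)
  expect_equal(net$k, 2L)
  expect_equal(which(net$adjacency[upper.tri(net$adjacency)] == 1),
               which(c(.9, .8, .6, .7, .5, .4) >= .8))

  # complete graph at s = 1
  expect_equal(binarize_at_sparsity(a, 1)$k, 6L)

  # canonical edge count at the highlight sparsity
  expect_equal(sparsity_edge_count(0.23), 524L)

  # scale invariance: multiplying |r| by c > 0 changes nothing
  set.seed(14)
  m <- matrix(rnorm(68 * 7), 68, dimnames = list(dk_region_names(), NULL))
  ab <- absolute_matrix(feature_correlation_matrix(m))
  n1 <- binarize_at_sparsity(ab, 0.23)
  ab2 <- ab * 0.37
  attr(ab2, "absolute") <- TRUE
  expect_identical(n1$adjacency, binarize_at_sparsity(ab2, 0.23)$adjacency)

  expect_error(binarize_at_sparsity(ab, 1e-5), "zero edges")
  expect_error(binarize_at_sparsity(abs(m %*% t(m)), 0.2), "absolute_matrix")
})

test_that("tie-breaking is lexicographic and deterministic", {
  a <- matrix(0.5, 4, 4)  # all off-diagonal ties
  diag(a) <- 1
  attr(a, "absolute") <- TRUE
  net <- binarize_at_sparsity(a, 1 / 3)  # k = 2
  # first two pairs in (i, j) lexicographic order: (1,2), (1,3)
  expect_equal(net$adjacency[1, 2], 1)
  expect_equal(net$adjacency[1, 3], 1)
  expect_equal(net$k, 2L)
})

test_that("sparsity sweep yields 21 nested networks with exact edge counts", {
  set.seed(2)
  m <- matrix(rnorm(68 * 7), 68, dimnames = list(dk_region_names(), NULL))
  ab <- absolute_matrix(feature_correlation_matrix(m))
  nets <- suppressWarnings(sparsity_sweep(ab))
  expect_length(nets, 21L)
  s_vals <- seq(0.20, 0.40, by = 0.01)
  expect_equal(vapply(nets, `[[`, 0L, "k"),
               vapply(s_vals, function(s) as.integer(floor(s * 2278 + 0.5)),
                      0L),
               ignore_attr = TRUE)
  expect_equal(nets[[1L]]$k, 456L)
  expect_equal(nets[[21L]]$k, 911L)

  # nestedness on many random matrices (small graphs for speed)
  set.seed(77)
  for (rep in 1:50) {
    mm <- matrix(rnorm(20 * 5), 20)
    ab2 <- absolute_matrix(feature_correlation_matrix(mm))
    sw <- suppressWarnings(sparsity_sweep(ab2, 0.2, 0.4, 0.05))
    for (i in seq_len(length(sw) - 1L)) {
      expect_true(all(sw[[i]]$adjacency <= sw[[i + 1L]]$adjacency))
    }
  }

  # step wider than the range: single network at s_min
  expect_length(suppressWarnings(sparsity_sweep(ab, 0.2, 0.25, 0.5)), 1L)
})

test_that("isolated-node reporting matches a direct degree scan", {
  a <- matrix(1, 5, 5) - diag(5)
  expect_length(check_no_isolated_nodes(make_net(a)), 0L)

  a[, 3] <- a[3, ] <- 0
  expect_equal(check_no_isolated_nodes(make_net(a)), "n3")

  set.seed(4)
  m <- matrix(rnorm(68 * 7), 68, dimnames = list(dk_region_names(), NULL))
  ab <- absolute_matrix(feature_correlation_matrix(m))
  net <- binarize_at_sparsity(ab, 0.20)
  expect_equal(check_no_isolated_nodes(net),
               names(which(rowSums(net$adjacency) == 0)))
})

test_that("relabeling regions permutes the connectivity consistently", {
  set.seed(33)
  m <- matrix(rnorm(12 * 5), 12, dimnames = list(paste0("r", 1:12), NULL))
  r <- feature_correlation_matrix(m)
  perm <- sample(12)
  r_perm <- feature_correlation_matrix(m[perm, ])
  expect_equal(r_perm, r[perm, perm], ignore_attr = TRUE)
})
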