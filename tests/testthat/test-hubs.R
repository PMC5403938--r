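test_that("mspBC and msjBC are plain per-node means", {
  bc <- matrix(rep(c(3, 7, 1), each = 21), nrow = 21,
               dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(mspBC(bc), c(a = 3, b = 7, c = 1))

  # 10 zeros and 11 tens average to 110/21
  bc2 <- matrix(c(rep(0, 10), rep(10, 11)), ncol = 1,
                dimnames = list(NULL, "a"))
  expect_equal(mspBC(bc2), c(a = 110 / 21))

  set.seed(71)
  r <- matrix(runif(21 * 68), 21, dimnames = list(NULL, dk_region_names()))
  expect_equal(mspBC(r), apply(r, 2, mean))

  r[3, 5] <- NA
  expect_error(mspBC(r), "missing")

  one <- matrix(1:5, nrow = 1, dimnames = list(NULL, letters[1:5]))
  expect_equal(msjBC(one), setNames(as.numeric(1:5), letters[1:5]))
  v <- c(a = 1, b = 5, c = 3)
  two <- rbind(v, -v + 2 * mean(v))
  expect_equal(msjBC(two), setNames(rep(mean(v), 3), names(v)))
})

test_that("the mean-plus-SD hub rule is strict and scale-invariant", {
  # mean 28, sample SD ~40.25, threshold ~68.25: only the outlier qualifies
  bc <- c(n1 = 10, n2 = 10, n3 = 10, n4 = 10, n5 = 100)
  expect_equal(identify_hubs(bc), "n5")
  expect_gt(100, mean(bc) + sd(bc))
  expect_lt(10, mean(bc) + sd(bc))

  expect_length(identify_hubs(c(a = 3, b = 3, c = 3)), 0L)
  expect_equal(identify_hubs(bc * 17.3), "n5")

  set.seed(72)
  for (rep in 1:50) {
    v <- setNames(rpois(12, 20), paste0("n", 1:12))
    expect_equal(identify_hubs(v),
                 names(v)[v > mean(v) + sd(v)])
  }
})

test_that("hub stability proportions count hub calls on each axis", {
  # single subject, 21 sparsities, 5 nodes; node 5 dominates at exactly 3
  regions <- paste0("n", 1:5)
  arr <- array(10, dim = c(1, 21, 5), dimnames = list("s1", NULL, regions))
  arr[1, 1:3, 5] <- 100
  hs <- hub_stability(arr)
  expect_equal(hs$proportions$prop_sparsities[5L], 3 / 21)
  expect_equal(hs$proportions$prop_sparsities[1:4], rep(0, 4))

  # flat tensor: no hubs anywhere
  flat <- array(4, dim = c(3, 5, 6),
                dimnames = list(NULL, NULL, paste0("n", 1:6)))
  hsf <- hub_stability(flat)
  expect_true(all(hsf$proportions$prop_sparsities == 0))
  expect_true(all(hsf$proportions$prop_subjects == 0))
  expect_length(hsf$grand_hubs, 0L)

  # grand mean commutes: mean over subjects of mspBC == mean over
  # sparsities of msjBC == grand_bc
  set.seed(73)
  arr <- array(runif(6 * 4 * 10), dim = c(6, 4, 10),
               dimnames = list(paste0("s", 1:6), NULL, paste0("n", 1:10)))
  hs <- hub_stability(arr)
  via_subjects <- colMeans(t(vapply(1:6, function(i) {
    mspBC(matrix(arr[i, , ], nrow = 4,
                 dimnames = list(NULL, paste0("n", 1:10))))
  }, numeric(10))))
  via_sparsities <- colMeans(t(vapply(1:4, function(j) {
    msjBC(matrix(arr[, j, ], nrow = 6,
                 dimnames = list(NULL, paste0("n", 1:10))))
  }, numeric(10))))
  expect_equal(unname(hs$grand_bc), unname(via_subjects))
  expect_equal(unname(via_subjects), unname(via_sparsities))
})

test_that("BC similarity is Pearson proximity with sane edge cases", {
  v <- c(1, 4, 2, 8)
  m <- rbind(v, v, v)
  expect_equal(unname(bc_similarity(m)), matrix(1, 3, 3))

  expect_equal(bc_similarity(rbind(v, -v))[1, 2], -1)
  expect_error(bc_similarity(rbind(v, rep(2, 4))), "constant")

  cs <- bc_similarity(rbind(a = c(1, 0), b = c(0, 1)), method = "cosine")
  expect_equal(cs[1, 2], 0)
  expect_equal(diag(cs), c(a = 1, b = 1))
})

test_that("BC profiles at adjacent sparsities are more similar than distant ones", {
  co <- small_cohort(n_subjects = 8L, n_sessions = 1L, seed = 74L)
  an <- analyze_cohort(co$subjects)
  # subject-mean BC per sparsity (21 x 68), as in the per-sparsity hub map
  msj <- apply(an$bc, c(2, 3), mean)
  sim <- bc_similarity(msj)
  lag_mean <- function(l) {
    mean(sim[cbind(seq_len(21 - l), seq_len(21 - l) + l)])
  }
  expect_gt(lag_mean(1), lag_mean(10))
})
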