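test_that("one-way ICC matches the explicit ANOVA decomposition", {
  # duplicated session: zero within-subject variance
  m <- cbind(c(4, 7, 9, 2), c(4, 7, 9, 2))
  res <- icc_oneway(m)
  expect_equal(res$icc, 1)
  expect_equal(res$sigma2_within, 0)

  # worked example, frozen from hand sums of squares:
  # MSB = 4.125, MSW = 0.375, ICC = 3.75 / 4.5 = 5/6
  m <- rbind(c(1, 2), c(2, 1), c(3, 3), c(5, 4))
  res <- icc_oneway(m)
  expect_equal(res$msb, 4.125)
  expect_equal(res$msw, 0.375)
  expect_equal(res$icc, 5 / 6)

  # independent oracle: mean squares from R's one-way ANOVA fit
  set.seed(81)
  m <- matrix(rnorm(30), 10, 3)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(10), 3)))
  ms <- summary(stats::aov(y ~ subj, data = d))[[1]][["Mean Sq"]]
  res <- icc_oneway(m)
  expect_equal(res$msb, ms[1])
  expect_equal(res$msw, ms[2])
  expect_equal(res$icc_raw, (ms[1] - ms[2]) / (ms[1] + 2 * ms[2]))
  expect_equal(res$p_value,
               stats::pf(ms[1] / ms[2], 9, 20, lower.tail = FALSE))

  expect_error(icc_oneway(matrix(5, 4, 2)), "identical")
  expect_error(icc_oneway(matrix(c(1, 2, NA, 4, 5, 6), 3, 2)), "missing")
  expect_error(icc_oneway(matrix(1:4, 2, 2)), "at least 3 subjects")
})

test_that("ICC recovers planted variance ratios and is affine-invariant", {
  set.seed(82)
  n <- 4000  # large n keeps estimator noise well inside the tolerance
  for (ratio in c(1, 3, 9)) {
    subj <- rnorm(n, sd = sqrt(ratio))
    m <- cbind(subj + rnorm(n), subj + rnorm(n))
    est <- icc_oneway(m)$icc
    expect_equal(est, ratio / (ratio + 1), tolerance = 0.05)
    # invariance under affine transformations of the measurement scale
    expect_equal(icc_oneway(m * 3.7 - 12)$icc, est)
    expect_equal(icc_oneway(m * -2)$icc, est)
  }
})

test_that("reliability labels follow the conventional cutpoints", {
  expect_equal(classify_reliability(c(0.83, 0.75, 0.6, 0.0, 0.59)),
               c("excellent", "good", "good", "below-good", "below-good"))
})

test_that("metric reliability tracks the planted session noise", {
  # noiseless sessions: the pipeline is deterministic, every ICC is 1
  co <- small_cohort(n_subjects = 6L, within_sd = 0, seed = 83L)
  an <- analyze_cohort(co$subjects, s_min = 0.2, s_max = 0.3, step = 0.05,
                       keep_bc = FALSE)
  d <- data.frame(subject = an$global$subject, session = an$global$session,
                  sparsity = an$global$sparsity, value = an$global$cp)
  rel <- metric_reliability(d)
  expect_true(all(rel$icc == 1))
  expect_equal(attr(rel, "mean_icc"), 1)

  # exchangeable subjects with independent sessions: ICC near zero
  co0 <- generate_cohort(synth_config(n_subjects = 40L, between_sd = 0,
                                      within_sd = 1, subject_strength_sd = 0,
                                      seed = 84L))
  an0 <- analyze_cohort(co0$subjects, s_min = 0.2, s_max = 0.3, step = 0.05,
                        keep_bc = FALSE)
  d0 <- data.frame(subject = an0$global$subject, session = an0$global$session,
                   sparsity = an0$global$sparsity, value = an0$global$cp)
  expect_lt(abs(attr(metric_reliability(d0), "mean_icc")), 0.25)
})

test_that("both BC reliability conventions are perfect for identical sessions", {
  regions <- paste0("n", 1:6)
  set.seed(85)
  b <- array(runif(5 * 3 * 6, 0, 30), dim = c(5, 3, 6),
             dimnames = list(paste0("s", 1:5), c("0.20", "0.25", "0.30"),
                             regions))
  rel <- bc_reliability(b, b)
  expect_true(all(rel$icc_node_mean == 1))
  expect_true(all(rel$icc_mean_node == 1))
  expect_equal(rel$sparsity, c(0.20, 0.25, 0.30))
})
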