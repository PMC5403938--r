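test_that("generation is deterministic and honors within_sd = 0", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- synth_config(n_subjects = 2L, seed = 91L)
  generate_cohort(cfg, dir = dir1)
  generate_cohort(cfg, dir = dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }

  # in-memory determinism
  co_a <- generate_cohort(cfg)
  co_b <- generate_cohort(cfg)
  expect_identical(co_a$subjects, co_b$subjects)

  # zero session noise: the two sessions of a subject are identical files
  dir3 <- withr::local_tempdir()
  generate_cohort(synth_config(n_subjects = 2L, within_sd = 0, seed = 92L),
                  dir = dir3)
  expect_identical(readLines(file.path(dir3, "sub001_ses1_lh.aparc.stats")),
                   readLines(file.path(dir3, "sub001_ses2_lh.aparc.stats")))
})

test_that("generated matrices satisfy downstream preconditions", {
  co <- small_cohort(n_subjects = 4L, seed = 93L)
  for (m in co$subjects) {
    expect_equal(dim(m), c(68L, 9L))
    expect_false(anyNA(m))
    expect_true(all(m[, c("NumVert", "SurfArea", "GrayVol")] > 0))
    expect_true(all(apply(m, 2, sd) > 0))      # no constant feature
    expect_silent(zscore_features(m))
  }
  # native magnitudes span the expected orders (1e-2 curvature, 1e3 counts)
  m <- co$subjects[[1L]]
  expect_gt(median(m[, "NumVert"]), 1000)
  expect_lt(median(abs(m[, "GausCurv"])), 0.1)

  # written fixtures parse back through the aparc.stats reader
  dir <- withr::local_tempdir()
  generate_cohort(synth_config(n_subjects = 1L, seed = 93L), dir = dir)
  parsed <- read_aparc_stats(file.path(dir, "sub001_ses1_lh.aparc.stats"),
                             "lh")
  expect_equal(dim(parsed), c(34L, 9L))
})

test_that("planted truth exposes modules, hubs and the ICC target", {
  cfg <- synth_config(n_subjects = 3L, n_modules = 2L,
                      between_sd = 3, within_sd = 1, seed = 94L)
  truth <- planted_truth(cfg)
  expect_setequal(unique(truth$modules), 1:2)
  expect_length(truth$modules, 68L)
  expect_equal(truth$expected_feature_icc, 0.9)
  expect_equal(truth$hub_regions, "lh_superiortemporal")

  expect_error(synth_config(hub_regions = "lh_nonexistent"), "atlas")
  expect_error(synth_config(between_sd = -1), "non-negative")
})

test_that("within-module similarity exceeds between-module similarity,
           with a gap monotone in the loading", {
  gap_for_loading <- function(loading, seed = 95L) {
    cfg <- synth_config(n_subjects = 5L, n_sessions = 1L, loading = loading,
                        seed = seed)
    co <- generate_cohort(cfg)
    mods <- planted_truth(cfg)$modules
    same <- outer(mods, mods, "==")
    hub <- rownames(co$subjects[[1L]]) %in% cfg$hub_regions
    gaps <- vapply(co$subjects, function(m) {
      a <- abs(cor(t(zscore_features(m))))
      ut <- upper.tri(a) & !outer(hub, hub, "|")
      mean(a[ut & same]) - mean(a[ut & !same])
    }, numeric(1))
    mean(gaps)
  }
  g_low <- gap_for_loading(0.6)
  g_mid <- gap_for_loading(1.2)
  g_high <- gap_for_loading(2.0)
  expect_gt(g_low, 0)
  expect_gt(g_mid, g_low)
  expect_gt(g_high, g_mid)
})
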