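# Synthetic two-session cohort generator.
#
# The generator emulates the statistical shape of FreeSurfer regional
# morphometry for a test-retest design:
#
#  * 68 regions x 9 features, feature magnitudes spanning roughly 1e-2
#    (Gaussian curvature) to 1e3 (vertex counts, volumes);
#  * planted inter-regional covariance: every region loads strongly on one
#    of `n_modules` module factors and moderately on a shared global
#    factor (the analogue of the global size factor that couples real
#    morphometry), so within-module feature vectors correlate more than
#    between-module ones.  Because the network construction z-scores each
#    feature ACROSS regions, any factor loaded identically by all regions
#    is removed by the centering; the global loadings therefore alternate
#    in sign between modules (same sign within a module), keeping the
#    cross-region mean loading at zero so the factor survives
#    standardization.  Absolute-value binarization makes the sign
#    irrelevant downstream;
#  * planted hub regions loading purely, and more strongly, on the global
#    factor, so |r| between a hub and any region exceeds the typical
#    cross-module |r| while within-module |r| stays highest.  With only
#    F ~ 9 features per vector, sampled correlations carry noise of about
#    0.3-0.4, so the hub's edge is an average effect: it is recovered by
#    the subject- and sparsity-averaged betweenness, not necessarily in
#    every single subject's network;
#  * a subject effect (SD `between_sd`) and session noise (SD `within_sd`)
#    on each feature's whole-brain level, so the expected whole-brain-mean
#    ICC is exactly between^2 / (between^2 + within^2);
#  * the same between/within ratio also sets the session stability of the
#    latent structure, so `within_sd = 0` reproduces sessions exactly.
#
# The structural component is centered across regions per feature before
# the level effects are added, so the planted covariance does not perturb
# the whole-brain mean and the ICC target holds exactly in expectation.

#' Default native-unit mapping for synthetic features
#'
#' Location/scale pairs that map standardized latent values to plausible
#' native units: log-normal for counts, areas, volumes and fold index
#' (strictly positive, magnitudes 1e1 to 1e3+), linear Gaussian for
#' thickness and curvature features (magnitudes 1e-2 to 1e0).
#'
#' @return Data frame with columns `feature`, `type`, `location`, `scale`.
#' @export
default_feature_scales <- function() {
  data.frame(
    feature  = morph_features(),
    type     = c("lognormal", "lognormal", "lognormal", "linear", "linear",
                 "linear", "linear", "lognormal", "linear"),
    location = c(3000, 2500, 7000, 2.5, 0.6, 0.13, 0.03, 30, 3.5),
    scale    = c(0.1, 0.1, 0.1, 0.15, 0.08, 0.02, 0.012, 0.1, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Synthetic cohort configuration
#'
#' @param n_subjects Number of subjects (default 55, a typical test-retest
#'   cohort size).
#' @param n_sessions Sessions per subject (default 2).
#' @param n_modules Number of planted covariance modules (default 8).
#' @param hub_regions Region labels engineered for high cross-module
#'   similarity (default left superior temporal gyrus).
#' @param loading Module factor loading of ordinary regions (default 1.2).
#' @param global_loading Magnitude of ordinary regions' loading on the
#'   shared global factor (default 1); the sign alternates between modules
#'   so the factor survives cross-region centering.
#' @param hub_loading Loading of hub regions on the global factor, their
#'   only structural loading (default 2.5; must exceed `global_loading`
#'   for the hub's cross-module correlations to stand out).
#' @param region_noise_sd SD of region-private noise in standardized units
#'   (default 0.6).
#' @param subject_strength_sd SD of the per-subject multiplier on factor
#'   loadings (default 0.15); gives subjects genuinely different network
#'   topology, the between-subject signal for metric reliability.
#' @param between_sd,within_sd Subject-level and session-level SDs of each
#'   feature's whole-brain level, standardized units (defaults 1 and 0.5:
#'   target feature ICC 0.8).  Their ratio also sets the session stability
#'   of the latent structure.
#' @param region_profile_sd SD of the fixed regional base profile shared by
#'   all subjects (default 0.5).
#' @param regions,features Node and feature sets (defaults: the 68-region
#'   atlas and the nine canonical features).
#' @param feature_scales Mapping from standardized latents to native units:
#'   data frame with columns `feature`, `type` (`"lognormal"` or
#'   `"linear"`), `location`, `scale`.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return Object of class `synth_config` (validated list).
#' @export
synth_config <- function(n_subjects = 55L, n_sessions = 2L, n_modules = 8L,
                         hub_regions = "lh_superiortemporal",
                         loading = 1.2, global_loading = 1, hub_loading = 2.5,
                         region_noise_sd = 0.6, subject_strength_sd = 0.15,
                         between_sd = 1, within_sd = 0.5,
                         region_profile_sd = 0.5,
                         regions = dk_region_names(),
                         features = morph_features(),
                         feature_scales = default_feature_scales(),
                         seed = 1L) {
  if (within_sd < 0 || between_sd < 0) {
    stopf("between_sd and within_sd must be non-negative")
  }
  bad_hub <- setdiff(hub_regions, regions)
  if (length(bad_hub) > 0L) {
    stopf("hub region(s) outside the atlas: %s",
          paste(bad_hub, collapse = ", "))
  }
  if (n_modules < 1L || n_modules > length(regions)) {
    stopf("n_modules must be between 1 and the number of regions")
  }
  missing_scales <- setdiff(features, feature_scales$feature)
  if (length(missing_scales) > 0L) {
    stopf("no feature_scales entry for: %s",
          paste(missing_scales, collapse = ", "))
  }
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_sessions = as.integer(n_sessions),
    n_modules = as.integer(n_modules), hub_regions = hub_regions,
    loading = loading, global_loading = global_loading,
    hub_loading = hub_loading,
    region_noise_sd = region_noise_sd,
    subject_strength_sd = subject_strength_sd,
    between_sd = between_sd, within_sd = within_sd,
    region_profile_sd = region_profile_sd,
    regions = regions, features = features,
    feature_scales = feature_scales, seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

# subject-share of session-stable variance; 1 when noiseless
.session_mix <- function(cfg) {
  tot <- cfg$between_sd^2 + cfg$within_sd^2
  if (tot == 0) 1 else cfg$between_sd^2 / tot
}

.module_assignment <- function(cfg) {
  stats::setNames(rep_len(seq_len(cfg$n_modules), length(cfg$regions)),
                  cfg$regions)
}

.to_native <- function(latent, cfg) {
  out <- latent
  for (f in colnames(latent)) {
    row <- cfg$feature_scales[cfg$feature_scales$feature == f, ]
    out[, f] <- if (row$type == "lognormal") {
      row$location * exp(row$scale * latent[, f])
    } else {
      row$location + row$scale * latent[, f]
    }
  }
  for (f in intersect(c("NumVert", "FoldInd"), colnames(out))) {
    out[, f] <- pmax(round(out[, f]), 1)
  }
  out
}

#' Generate a synthetic two-session cohort
#'
#' Draws the cohort described by a [synth_config()].  With `dir = NULL` the
#' matrices stay in memory; with a directory, per-hemisphere aparc.stats
#' dialect files and a `manifest.csv` are written, so the whole parsing
#' path is exercised.  Same seed, byte-identical output.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory for on-disk fixtures.
#' @return Object of class `synth_cohort`: list with `subjects` (list of
#'   68 x 9 feature matrices with subject/session attributes, named
#'   `<subject>_<session>`), `manifest` (data frame) and `config`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  regions <- config$regions
  feats <- config$features
  n_r <- length(regions)
  n_f <- length(feats)
  n_m <- config$n_modules
  modules <- .module_assignment(config)
  rho <- .session_mix(config)

  set.seed(config$seed)
  mu <- matrix(stats::rnorm(n_r * n_f, sd = config$region_profile_sd),
               n_r, n_f, dimnames = list(regions, feats))
  # columns 1..n_m are module factors, column n_m + 1 the global factor;
  # global loadings alternate sign by module so that cross-region centering
  # (the z-score step of the construction) does not cancel the factor
  n_fac <- n_m + 1L
  loadings <- matrix(0, n_r, n_fac, dimnames = list(regions, NULL))
  loadings[cbind(seq_len(n_r), modules)] <- config$loading
  loadings[, n_fac] <- config$global_loading * ifelse(modules %% 2L == 0L, -1, 1)
  loadings[config$hub_regions, ] <- 0
  loadings[config$hub_regions, n_fac] <- config$hub_loading

  subjects <- list()
  manifest <- NULL
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("sub%03d", i)
    trait <- max(0.2, 1 + stats::rnorm(1, sd = config$subject_strength_sd))
    g_subj <- matrix(stats::rnorm(n_fac * n_f), n_fac, n_f)
    e_subj <- matrix(stats::rnorm(n_r * n_f), n_r, n_f)
    alpha <- stats::rnorm(n_f, sd = config$between_sd)
    for (t in seq_len(config$n_sessions)) {
      g_sess <- matrix(stats::rnorm(n_fac * n_f), n_fac, n_f)
      e_sess <- matrix(stats::rnorm(n_r * n_f), n_r, n_f)
      w <- stats::rnorm(n_f, sd = config$within_sd)
      g <- sqrt(rho) * g_subj + sqrt(1 - rho) * g_sess
      e <- sqrt(rho) * e_subj + sqrt(1 - rho) * e_sess
      struct <- trait * (loadings %*% g) + config$region_noise_sd * e
      struct <- sweep(struct, 2L, colMeans(struct))
      latent <- mu + struct +
        matrix(alpha + w, n_r, n_f, byrow = TRUE)
      dimnames(latent) <- list(regions, feats)
      native <- .to_native(latent, config)
      m <- subject_features(native, subject_id = sid, session_id = t)
      subjects[[paste0(sid, "_", t)]] <- m

      lh_path <- rh_path <- NA_character_
      if (!is.null(dir)) {
        hemis <- split_hemispheres(m)
        lh_path <- sprintf("%s_ses%d_lh.aparc.stats", sid, t)
        rh_path <- sprintf("%s_ses%d_rh.aparc.stats", sid, t)
        write_aparc_stats(hemis$lh, file.path(dir, lh_path), "lh")
        write_aparc_stats(hemis$rh, file.path(dir, rh_path), "rh")
      }
      manifest <- rbind(manifest, data.frame(
        subject_id = sid, session_id = t,
        lh_path = lh_path, rh_path = rh_path, stringsAsFactors = FALSE))
    }
  }
  if (!is.null(dir)) {
    write_cohort_manifest(manifest, file.path(dir, "manifest.csv"))
  }
  structure(list(subjects = subjects, manifest = manifest, config = config),
            class = "synth_cohort")
}

#' Ground truth of a synthetic configuration
#'
#' Machine-readable planted truth for recovery tests: the module partition,
#' the engineered hub regions, and the expected whole-brain feature ICC
#' implied by the variance ratio.
#'
#' @param config A [synth_config()].
#' @return List with `modules` (named integer vector), `hub_regions` and
#'   `expected_feature_icc`.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  tot <- config$between_sd^2 + config$within_sd^2
  list(
    modules = .module_assignment(config),
    hub_regions = config$hub_regions,
    expected_feature_icc = if (tot == 0) NA_real_ else config$between_sd^2 / tot
  )
}
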