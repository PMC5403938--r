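# End-to-end orchestration.  Stages exchange plain text artifacts
# (CSV/TSV) in an output directory, so any stage can be inspected or
# replaced; every stochastic stage takes its seed from the pipeline config.

#' Pipeline configuration
#'
#' Default settings reproduce the method's canonical analysis: sparsity
#' sweep 0.20-0.40 in steps of 0.01 (21 networks), highlight sparsity 0.23,
#' feature screen threshold p < 0.1, 100 null networks, FDR level 0.05.
#'
#' @param out_dir Directory for stage artifacts.
#' @param manifest Path to a cohort manifest CSV (defaults to
#'   `<out_dir>/cohort/manifest.csv`, where [run_simulate()] puts it).
#' @param features Optional explicit feature subset; `NULL` uses the screen
#'   result when available, otherwise all nine features.
#' @param s_min,s_max,step Sparsity sweep.
#' @param highlight Sparsity highlighted in reports (default 0.23).
#' @param p_max Feature screen significance threshold.
#' @param n_null Null networks per subject and sparsity.
#' @param q FDR level.
#' @param seed Master seed for all stochastic stages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, manifest = NULL, features = NULL,
                            s_min = 0.20, s_max = 0.40, step = 0.01,
                            highlight = 0.23, p_max = 0.1,
                            n_null = 100L, q = 0.05, seed = 1L) {
  structure(
    list(out_dir = out_dir,
         manifest = manifest %||% file.path(out_dir, "cohort", "manifest.csv"),
         features = features, s_min = s_min, s_max = s_max, step = step,
         highlight = highlight, p_max = p_max,
         n_null = as.integer(n_null), q = q, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

need_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stopf("missing artifact '%s'; run %s first", path, stage)
  }
  path
}

.sparsities <- function(cfg) {
  seq(cfg$s_min, cfg$s_max + 1e-12, by = cfg$step)
}

.load_pipeline_cohort <- function(cfg) {
  man <- read_cohort_manifest(need_artifact(cfg$manifest, "run_simulate"))
  load_cohort(man, base_dir = dirname(cfg$manifest))
}

.selected_features <- function(cfg) {
  if (!is.null(cfg$features)) return(cfg$features)
  sel_path <- file.path(cfg$out_dir, "selected_features.txt")
  if (file.exists(sel_path)) readLines(sel_path) else morph_features()
}

#' Simulate a cohort into the pipeline layout
#'
#' @param cfg A [pipeline_config()].
#' @param synth A [synth_config()]; its seed defaults to the pipeline seed.
#' @return The cohort directory, invisibly.
#' @export
run_simulate <- function(cfg, synth = NULL) {
  synth <- synth %||% synth_config(seed = cfg$seed)
  dir <- file.path(cfg$out_dir, "cohort")
  generate_cohort(synth, dir = dir)
  invisible(dir)
}

#' Screen features for test-retest robustness and record the selection
#'
#' Writes `screen.csv` and `selected_features.txt` under the output
#' directory.
#'
#' @param cfg A [pipeline_config()].
#' @return The screen data frame, invisibly.
#' @export
run_screen <- function(cfg) {
  cohort <- .load_pipeline_cohort(cfg)
  screen <- screen_feature_reliability(cohort)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(screen, file.path(cfg$out_dir, "screen.csv"),
                   row.names = FALSE)
  sel <- select_features(screen, p_max = cfg$p_max)
  writeLines(sel, file.path(cfg$out_dir, "selected_features.txt"))
  invisible(screen)
}

#' Build per-subject absolute connectivity matrices
#'
#' Z-scores the selected features within each subject/session, correlates
#' feature vectors, takes absolute values, and writes one labeled TSV per
#' subject-session under `<out>/connectomes/`.
#'
#' @param cfg A [pipeline_config()].
#' @return Directory of connectome matrices, invisibly.
#' @export
run_build <- function(cfg) {
  cohort <- .load_pipeline_cohort(cfg)
  feats <- .selected_features(cfg)
  dir <- file.path(cfg$out_dir, "connectomes")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in cohort) {
    z <- zscore_features(m[, feats, drop = FALSE])
    a <- absolute_matrix(feature_correlation_matrix(z))
    write_matrix(a, file.path(dir, sprintf("%s_ses%d.tsv",
                                           attr(m, "subject_id"),
                                           attr(m, "session_id"))))
  }
  invisible(dir)
}

.connectome_units <- function(cfg) {
  dir <- file.path(cfg$out_dir, "connectomes")
  need_artifact(dir, "run_build")
  files <- list.files(dir, pattern = "_ses[0-9]+\\.tsv$", full.names = TRUE)
  if (length(files) == 0L) stopf("no connectome matrices in %s; run run_build first", dir)
  info <- regmatches(basename(files),
                     regexec("^(.+)_ses([0-9]+)\\.tsv$", basename(files)))
  data.frame(path = files,
             subject = vapply(info, `[`, "", 2L),
             session = as.integer(vapply(info, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

.read_abs_matrix <- function(path) {
  a <- read_matrix(path)
  attr(a, "absolute") <- TRUE
  a
}

#' Compute sweep metrics for every connectome
#'
#' Writes `metrics.csv` (subject, session, sparsity, k, cp, lp) and
#' `bc.csv` (subject, session, sparsity, one column per region).
#'
#' @param cfg A [pipeline_config()].
#' @return The metrics data frame, invisibly.
#' @export
run_metrics <- function(cfg) {
  units <- .connectome_units(cfg)
  glob <- NULL
  bc <- NULL
  for (i in seq_len(nrow(units))) {
    a <- .read_abs_matrix(units$path[[i]])
    nets <- suppressWarnings(
      sparsity_sweep(a, cfg$s_min, cfg$s_max, cfg$step))
    sm <- sweep_metrics(nets)
    glob <- rbind(glob, cbind(subject = units$subject[[i]],
                              session = units$session[[i]], sm$global))
    bc <- rbind(bc, cbind(
      data.frame(subject = units$subject[[i]], session = units$session[[i]],
                 sparsity = sm$global$sparsity),
      as.data.frame(sm$bc)))
  }
  utils::write.csv(glob, file.path(cfg$out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(bc, file.path(cfg$out_dir, "bc.csv"), row.names = FALSE)
  invisible(glob)
}

#' Small-world configurations against matched nulls
#'
#' For every subject-session and sparsity, computes gamma, lambda, sigma
#' over `n_null` degree-preserving random networks
#' (`smallworld.csv`), then compares real versus null Cp and Lp across
#' subjects per sparsity with pooled t-tests and FDR correction
#' (`comparison.csv`, session 1).
#'
#' @param cfg A [pipeline_config()].
#' @return The small-world data frame, invisibly.
#' @export
run_nulls <- function(cfg) {
  units <- .connectome_units(cfg)
  rows <- NULL
  for (i in seq_len(nrow(units))) {
    a <- .read_abs_matrix(units$path[[i]])
    nets <- suppressWarnings(
      sparsity_sweep(a, cfg$s_min, cfg$s_max, cfg$step))
    for (j in seq_along(nets)) {
      sw <- small_world(nets[[j]], n_null = cfg$n_null,
                        seed = cfg$seed + i * 1000L + j)
      rows <- rbind(rows, data.frame(
        subject = units$subject[[i]], session = units$session[[i]],
        sparsity = as.numeric(names(nets)[[j]]),
        cp = sw$cp, lp = sw$lp, cp_rand = sw$cp_rand, lp_rand = sw$lp_rand,
        gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma))
    }
  }
  utils::write.csv(rows, file.path(cfg$out_dir, "smallworld.csv"),
                   row.names = FALSE)
  s1 <- rows[rows$session == 1L, ]
  mk <- function(col) {
    m <- tapply(s1[[col]], list(s1$subject, sprintf("%.2f", s1$sparsity)),
                identity)
    m[, order(as.numeric(colnames(m))), drop = FALSE]
  }
  cmp_cp <- compare_sweep(mk("cp"), mk("cp_rand"), q = cfg$q)
  cmp_lp <- compare_sweep(mk("lp"), mk("lp_rand"), q = cfg$q)
  cmp <- rbind(cbind(metric = "cp", cmp_cp), cbind(metric = "lp", cmp_lp))
  utils::write.csv(cmp, file.path(cfg$out_dir, "comparison.csv"),
                   row.names = FALSE)
  invisible(rows)
}

.bc_array_from_csv <- function(bc, session) {
  b <- bc[bc$session == session, ]
  regions <- setdiff(colnames(b), c("subject", "session", "sparsity"))
  subjects <- sort(unique(b$subject))
  spars <- sort(unique(b$sparsity))
  arr <- array(NA_real_, dim = c(length(subjects), length(spars),
                                 length(regions)),
               dimnames = list(subjects, sprintf("%.2f", spars), regions))
  for (r in seq_len(nrow(b))) {
    arr[b$subject[[r]], sprintf("%.2f", b$sparsity[[r]]), ] <-
      as.numeric(b[r, regions])
  }
  arr
}

#' Hub identification and stability report
#'
#' Aggregates session-1 betweenness over sparsities and subjects, applies
#' the mean-plus-SD hub rule on every axis, and writes `hubs.csv` plus a
#' BrainNet Viewer `.node`/`.edge` export of the grand-mean hub map (node
#' size = grand-mean BC, edges = group-mean network at the highlight
#' sparsity).
#'
#' @param cfg A [pipeline_config()].
#' @return The hub stability list, invisibly.
#' @export
run_hubs <- function(cfg) {
  bc_path <- need_artifact(file.path(cfg$out_dir, "bc.csv"), "run_metrics")
  bc <- utils::read.csv(bc_path, check.names = FALSE)
  arr <- .bc_array_from_csv(bc, session = 1L)
  hs <- hub_stability(arr)
  report <- hs$proportions
  report$grand_bc <- hs$grand_bc[report$region]
  report$grand_hub <- report$region %in% hs$grand_hubs
  utils::write.csv(report, file.path(cfg$out_dir, "hubs.csv"),
                   row.names = FALSE)

  units <- .connectome_units(cfg)
  units <- units[units$session == 1L, ]
  mats <- lapply(units$path, .read_abs_matrix)
  mean_abs <- Reduce(`+`, mats) / length(mats)
  attr(mean_abs, "absolute") <- TRUE
  if (identical(sort(rownames(mean_abs)), sort(dk_region_names()))) {
    net <- binarize_at_sparsity(mean_abs, cfg$highlight)
    export_brainnet(hs$grand_bc, net,
                    prefix = file.path(cfg$out_dir, "hubs_grand"))
  }
  invisible(hs)
}

#' Test-retest reliability of Cp, Lp and betweenness
#'
#' Requires metrics for two sessions per subject; writes
#' `reliability.csv` with per-sparsity ICC for Cp and Lp and the two BC
#' conventions of [bc_reliability()].
#'
#' @param cfg A [pipeline_config()].
#' @return The reliability data frame, invisibly.
#' @export
run_icc <- function(cfg) {
  mpath <- need_artifact(file.path(cfg$out_dir, "metrics.csv"), "run_metrics")
  metrics <- utils::read.csv(mpath)
  if (!all(c(1L, 2L) %in% metrics$session)) {
    stopf("reliability needs two sessions per subject")
  }
  out <- NULL
  for (metric in c("cp", "lp")) {
    d <- data.frame(subject = metrics$subject, session = metrics$session,
                    sparsity = metrics$sparsity, value = metrics[[metric]])
    rel <- metric_reliability(d)
    out <- rbind(out, cbind(metric = metric,
                            rel[, c("sparsity", "icc", "f_statistic",
                                    "p_value", "label")]))
  }
  bc <- utils::read.csv(file.path(cfg$out_dir, "bc.csv"),
                        check.names = FALSE)
  b1 <- .bc_array_from_csv(bc, 1L)
  b2 <- .bc_array_from_csv(bc, 2L)
  bcrel <- bc_reliability(b1, b2)
  out <- rbind(out,
               data.frame(metric = "bc_node_mean", sparsity = bcrel$sparsity,
                          icc = bcrel$icc_node_mean, f_statistic = NA,
                          p_value = NA,
                          label = classify_reliability(bcrel$icc_node_mean)),
               data.frame(metric = "bc_mean_node", sparsity = bcrel$sparsity,
                          icc = bcrel$icc_mean_node, f_statistic = NA,
                          p_value = NA,
                          label = classify_reliability(bcrel$icc_mean_node)))
  utils::write.csv(out, file.path(cfg$out_dir, "reliability.csv"),
                   row.names = FALSE)
  invisible(out)
}

#' Run the full pipeline on a simulated cohort
#'
#' @param cfg A [pipeline_config()].
#' @param synth Optional [synth_config()] passed to [run_simulate()].
#' @return `cfg`, invisibly.
#' @export
run_all <- function(cfg, synth = NULL) {
  run_simulate(cfg, synth)
  run_screen(cfg)
  run_build(cfg)
  run_metrics(cfg)
  run_nulls(cfg)
  run_hubs(cfg)
  run_icc(cfg)
  invisible(cfg)
}

#' In-memory cohort analysis
#'
#' Convenience path used by simulations and tests: takes a list of subject
#' feature matrices and returns sweep metrics without touching disk.
#'
#' @param mats List of subject feature matrices (with subject/session
#'   attributes).
#' @param features Feature subset (default: all columns).
#' @param s_min,s_max,step Sparsity sweep.
#' @param keep_bc Collect the betweenness tensor (default TRUE).
#' @return List with `global` (data frame subject, session, sparsity, k,
#'   cp, lp) and `bc` (array units x sparsities x nodes, unit names
#'   `<subject>_<session>`), plus `units` (data frame).
#' @export
analyze_cohort <- function(mats, features = NULL,
                           s_min = 0.20, s_max = 0.40, step = 0.01,
                           keep_bc = TRUE) {
  glob <- NULL
  bc_rows <- list()
  units <- data.frame(subject = character(0), session = integer(0))
  for (m in mats) {
    sid <- attr(m, "subject_id")
    ses <- attr(m, "session_id")
    sel <- if (is.null(features)) m else m[, features, drop = FALSE]
    z <- zscore_features(sel)
    a <- absolute_matrix(feature_correlation_matrix(z))
    nets <- suppressWarnings(sparsity_sweep(a, s_min, s_max, step))
    sm <- sweep_metrics(nets)
    glob <- rbind(glob, cbind(subject = sid, session = ses, sm$global))
    if (keep_bc) bc_rows[[paste0(sid, "_", ses)]] <- sm$bc
    units <- rbind(units, data.frame(subject = sid, session = ses))
  }
  bc <- NULL
  if (keep_bc) {
    spars <- rownames(bc_rows[[1L]])
    regions <- colnames(bc_rows[[1L]])
    bc <- array(NA_real_,
                dim = c(length(bc_rows), length(spars), length(regions)),
                dimnames = list(names(bc_rows), spars, regions))
    for (u in seq_along(bc_rows)) bc[u, , ] <- bc_rows[[u]]
  }
  list(global = glob, bc = bc, units = units)
}
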