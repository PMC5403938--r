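# Betweenness-centrality hub identification.
#
# A node is a hub when its BC strictly exceeds mean(BC) + sd(BC) over the
# whole network (sample sd, denominator n - 1).  Two aggregations feed the
# rule: mspBC averages a subject's nodal BC over the sparsity sweep (hubs
# per subject); msjBC averages nodal BC over subjects at one sparsity (hubs
# per sparsity).  The grand mean over both axes gives the cohort-level hub
# map.

#' Mean nodal betweenness across the sparsity sweep (mspBC)
#'
#' @param bc Matrix sparsities x nodes of one subject's BC values; no
#'   missing entries allowed (every sparsity of the sweep must be present).
#' @return Named numeric vector of length N (per-node mean).
#' @export
mspBC <- function(bc) {
  stopifnot(is.matrix(bc))
  if (anyNA(bc)) stopf("BC missing at some sparsity; complete the sweep first")
  colMeans(bc)
}

#' Mean nodal betweenness across subjects at one sparsity (msjBC)
#'
#' @param bc Matrix subjects x nodes of BC values at a single sparsity.
#' @return Named numeric vector of length N.
#' @export
msjBC <- function(bc) {
  stopifnot(is.matrix(bc), nrow(bc) >= 1L)
  if (anyNA(bc)) stopf("BC missing for some subject")
  colMeans(bc)
}

#' Identify hubs by the mean-plus-SD rule
#'
#' Hubs are the nodes whose BC strictly exceeds `mean(bc) + sd(bc)`
#' (sample standard deviation).  The rule is scale-invariant and may return
#' an empty set (e.g. for constant BC, where sd = 0 and the inequality is
#' strict).
#'
#' @param bc Named numeric vector of nodal BC values (length >= 2).
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return Character vector of hub labels (positions if unnamed).
#' @export
identify_hubs <- function(bc, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(bc) < 2L) stopf("need at least 2 nodes")
  s <- stats::sd(bc)
  if (sd_type == "population") {
    s <- s * sqrt((length(bc) - 1) / length(bc))
  }
  hub <- bc > mean(bc) + s
  if (is.null(names(bc))) as.character(which(hub)) else names(bc)[hub]
}

#' Hub stability across sparsities and subjects
#'
#' From a cohort BC tensor, computes per region (a) the proportion of
#' sparsities at which the region is a hub of the subject-averaged network
#' (msjBC hub calls) and (b) the proportion of subjects for which the
#' region is a hub of the sparsity-averaged BC (mspBC hub calls), plus the
#' grand-mean BC vector and its hub set.
#'
#' @param bc_array 3-d array subjects x sparsities x nodes with dimnames.
#' @param prop_cut Proportion threshold for the `candidates` listing
#'   (default 0.2: hubs over >20% of sparsities or subjects).
#' @return List with `proportions` (data frame: `region`,
#'   `prop_sparsities`, `prop_subjects`), `grand_bc` (named vector),
#'   `grand_hubs` (labels) and `candidates` (regions exceeding `prop_cut`
#'   on either axis).
#' @export
hub_stability <- function(bc_array, prop_cut = 0.2) {
  stopifnot(length(dim(bc_array)) == 3L)
  n_subj <- dim(bc_array)[[1L]]
  n_spar <- dim(bc_array)[[2L]]
  regions <- dimnames(bc_array)[[3L]]

  hub_ind_sparsity <- vapply(seq_len(n_spar), function(j) {
    m <- msjBC(matrix(bc_array[, j, ], nrow = n_subj,
                      dimnames = list(NULL, regions)))
    regions %in% identify_hubs(m)
  }, logical(length(regions)))
  hub_ind_subject <- vapply(seq_len(n_subj), function(i) {
    v <- mspBC(matrix(bc_array[i, , ], nrow = n_spar,
                      dimnames = list(NULL, regions)))
    regions %in% identify_hubs(v)
  }, logical(length(regions)))

  prop_sp <- rowMeans(hub_ind_sparsity)
  prop_su <- rowMeans(hub_ind_subject)
  grand_bc <- apply(bc_array, 3L, mean)
  list(
    proportions = data.frame(region = regions,
                             prop_sparsities = prop_sp,
                             prop_subjects = prop_su,
                             stringsAsFactors = FALSE),
    grand_bc = grand_bc,
    grand_hubs = identify_hubs(grand_bc),
    candidates = regions[prop_sp > prop_cut | prop_su > prop_cut]
  )
}

#' Pairwise similarity of BC vectors
#'
#' Proximity matrix between nodal-BC vectors (e.g. one vector per sparsity
#' or per subject), used to visualize how stable the BC profile is along
#' either axis.  Pearson correlation is the default interval-data proximity
#' measure; cosine similarity and a Euclidean-distance-based similarity
#' `1 / (1 + d)` are offered.
#'
#' @param vectors Matrix with one BC vector per row (>= 2 rows).
#' @param method `"pearson"`, `"cosine"` or `"euclidean"`.
#' @return Symmetric similarity matrix with unit diagonal (for Pearson and
#'   cosine).
#' @export
bc_similarity <- function(vectors, method = c("pearson", "cosine",
                                              "euclidean")) {
  method <- match.arg(method)
  stopifnot(is.matrix(vectors), nrow(vectors) >= 2L)
  if (method == "pearson") {
    row_sd <- apply(vectors, 1L, stats::sd)
    if (any(row_sd == 0)) {
      stopf("constant BC vector(s) at row(s): %s",
            paste(which(row_sd == 0), collapse = ", "))
    }
    return(stats::cor(t(vectors)))
  }
  if (method == "cosine") {
    nrm <- sqrt(rowSums(vectors^2))
    if (any(nrm == 0)) stopf("zero BC vector; cosine undefined")
    v <- vectors / nrm
    return(v %*% t(v))
  }
  d <- as.matrix(stats::dist(vectors))
  1 / (1 + d)
}
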