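---
title: "Individual morphological brain networks from multiple morphometric features"
author: "morphnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual morphological brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

Most morphological brain networks are population-based: a single feature
(cortical thickness, gray-matter volume) is correlated *across subjects*,
yielding one network per group and discarding individual differences.
`morphnet` implements the individual-based alternative: each subject gets
their own connectome, built from the covariance of *multiple* morphometric
features *across regions within that one scan*.

The construction, per subject and session:

1. **Regional descriptor.** For each of the 68 Desikan–Killiany cortical
   regions (34 gyrus-based parcels per hemisphere), concatenate F
   morphometric features into a feature vector. The nine candidate
   features are vertex count, surface area (mm²), gray-matter volume
   (mm³), mean and SD of cortical thickness (mm), mean curvature (mm⁻¹),
   Gaussian curvature (mm⁻²), fold index and curvature index. All are
   taken in native space exactly as the surface reconstruction reports
   them; no unit conversion is applied.
2. **Standardization.** Feature magnitudes span roughly 10⁻² to 10³, so
   each feature is z-scored across the 68 regions (sample SD, denominator
   n − 1) before correlating — `zscore_features()`. Standardization is
   strictly within subject/session: pooling across subjects would leak
   population information into a single-subject network. A pooled mode is
   available through the `pooled` argument for users who explicitly want
   it.
3. **Connectivity.** The edge weight between regions *i* and *j* is the
   Pearson correlation of their F-long standardized feature vectors —
   `feature_correlation_matrix()`. Absolute values are taken
   (`absolute_matrix()`) so that strong negative covariance also counts
   as connectivity.
4. **Binarization.** The |r| matrix is thresholded to an unweighted,
   undirected graph at a *sparsity* s: the fraction of realized edges
   among the N(N−1)/2 = 2278 possible pairs. Because no single sparsity
   is privileged, metrics are traced over a sweep, 20 % to 40 % in 1 %
   steps (21 networks), with 23 % highlighted for comparison with the
   literature — `sparsity_sweep()`.

### Graph measures

* **Clustering** Cᵢ = 2Eᵢ / kᵢ(kᵢ − 1), zero for degree < 2; Cp is the
  unweighted mean over nodes.
* **Characteristic path length** uses Newman's harmonic-mean form,
  Lp = [ (1/N(N−1)) Σ_{i≠j} 1/d(i,j) ]⁻¹. Thresholded brain graphs are
  not always connected; the harmonic form absorbs disconnected pairs as
  zero contributions instead of producing an infinite Lp, which is
  exactly why it is used here.
* **Small-world configurations** γ = Cp/Cp_rand, λ = Lp/Lp_rand,
  σ = γ/λ, with the null means taken over matched random networks.
  σ > 1 is the usual one-number small-worldness criterion.
* **Betweenness centrality** (Freeman, unnormalized, each unordered pair
  counted once) drives hub identification; degree deliberately does not,
  since it sees only a node's own edges, not its role on shortest paths.
  A node is a **hub** when BC strictly exceeds mean(BC) + SD(BC).
  Because hub calls vary with both threshold and person, BC is averaged
  over the sweep per subject (`mspBC()`) and over subjects per sparsity
  (`msjBC()`), and stability is reported as the proportion of
  sparsities/subjects in which each region passes the rule
  (`hub_stability()`).
* **Reliability.** For two-session designs, every quantity of interest
  gets a one-way random-effects intraclass correlation,
  ICC = σ²between/(σ²between + σ²within), estimated by the ANOVA
  decomposition ICC(1,1) = (MSB − MSW)/(MSB + (k−1) MSW)
  (`icc_oneway()`). ICC > 0.75 is labelled excellent, 0.6–0.75 good.

## Tunable parameters that matter

| parameter | default | why |
|---|---|---|
| sparsity sweep | 0.20–0.40, step 0.01 | minimum chosen so no node is isolated, maximum so small-worldness holds; 21 thresholds |
| highlight sparsity | 0.23 | the conventional comparison point across network studies |
| feature screen `p_max` | 0.1 | reproduces the reference 9 → 7 feature reduction on the shipped screen table; no principled universal value exists, so both `p_max` and an ICC floor are exposed |
| `n_null` | 100 | null networks per subject × sparsity; the SD of the null mean shrinks as 1/√n_null |
| null model | degree-preserving rewiring | "same nodes and edges" in this literature conventionally also preserves the degree sequence (Maslov–Sneppen double-edge swaps); an Erdős–Rényi option exists |
| swap budget | 10 × k attempted swaps | standard mixing heuristic |
| FDR level `q` | 0.05 | Benjamini–Hochberg step-up across the sweep |
| hub SD | sample (n − 1) | the rule's SD flavour is not standardized; population SD available |

## Numerical choices, ties and degenerate inputs

* **Edge count rounding**: k = round(s · 2278) with half rounded away
  from zero (so s = 0.23 gives exactly k = 524). R's default
  round-half-to-even would give different counts at some sparsities.
* **Ties in |r|** are broken by lexicographic (i, j) order. On real data
  ties have measure zero; in tests they are certain, and a fixed total
  order makes results reproducible and edge sets *nested* along the
  sweep. It also makes binarization invariant to positive rescaling of
  |r|.
* **Constant columns/rows** (a feature constant across regions, a region
  constant across features, all-identical ICC tables, constant BC
  vectors in a similarity matrix) are errors that name the offender,
  never silent NaNs. An all-equal BC vector yields an *empty* hub set
  (SD = 0 and the rule is strict), which is valid.
* **Negative variance components** in the ICC ANOVA are floored at zero
  for the reported ICC; the raw estimate is returned alongside for
  transparency in small samples.
* Parsing of `aparc.stats` files is column-name driven from the
  `# ColHeaders` line; column permutations parse identically and unknown
  extra columns are ignored (forward compatibility with other
  FreeSurfer versions).

## The synthetic cohort: what it emulates, and what a green test proves

Real inputs are FreeSurfer tables from T1 scans; none ship with the
package. `generate_cohort()` draws a cohort whose *statistical shape*
matches what the pipeline cares about:

* 68 × 9 matrices with native magnitudes spanning 10⁻² to 10³
  (log-normal counts/areas/volumes, Gaussian thickness/curvature);
* planted modular covariance: each region loads on one of 8 module
  factors (loading 1.2) plus region-private noise (SD 0.6), so
  within-module |r| exceeds between-module |r| with a gap monotone in
  the loading;
* a shared **global factor** — the analogue of the overall size factor
  that couples real morphometry — with loading magnitude 1 whose sign
  alternates between modules. The sign alternation matters: the
  construction z-scores each feature *across regions*, which subtracts
  any component loaded identically by all regions; a sign-balanced
  loading survives the centering, and absolute-value binarization makes
  the sign irrelevant downstream;
* planted **hubs** (default: left superior temporal gyrus) loading
  purely and more strongly (2.5) on the global factor. Their |r| to
  every region then exceeds typical cross-module |r|, so they bridge the
  thresholded graph. A geometric fact worth recording: a hub loading on
  M orthogonal module factors can correlate with each module at most
  1/√M, which drowns in the ±0.3–0.4 sampling noise that Pearson
  correlations over 9-long vectors carry — that design does *not* plant
  a recoverable hub, and the global-factor construction is used instead;
* a two-session test–retest design: subject-level (`between_sd`, default
  1) and session-level (`within_sd`, default 0.5) effects on each
  feature's whole-brain level, so the expected whole-brain feature ICC
  is exactly between²/(between² + within²) = 0.8 at the defaults — in
  the "excellent" range typical of surface-based morphometry. The same
  ratio sets the session stability of the latent structure, so
  `within_sd = 0` reproduces sessions byte-identically. The structural
  component is centered across regions per feature before level effects
  are added, which is what makes the ICC target exact rather than
  approximate. Defaults use 55 subjects scanned twice, a typical
  test–retest cohort.

Because correlations are estimated from only F ≈ 9 features, individual
networks are intrinsically noisy; the planted hub is an *average* effect,
recovered by the subject- and sparsity-averaged betweenness rather than
in every single network — which mirrors how the method behaves on real
cohorts, where hub calls vary strongly between subjects but stabilize
under averaging.

What generated data cannot establish: agreement with any particular real
cohort's numbers (the external benchmark values Cp ≈ 0.62, Lp ≈ 2.23,
σ ≈ 1.52, ICC(Cp) ≈ 0.83 at s = 0.23 reported for a 55-subject OASIS
cohort require that cohort and its exact FreeSurfer version), scanner
effects, age/sex structure, or cortical geometry. Green tests establish
that the *machinery* is correct (graph measures match brute-force
oracles; ICC recovers planted variance ratios; BH controls FDR;
Watts–Strogatz lattices are detected as small-world and Erdős–Rényi
graphs are not; planted hubs are recovered) — not that any biological
claim holds.

## Design choices where the method description is genuinely open

* **Feature selection rule.** The reference screen keeps Gaussian
  curvature (p = 0.076) and mean thickness (p = 0.053) but drops fold
  index (ICC 0.73, p = 0.76) and curvature index (ICC 0.36, p = 0.29).
  A p < 0.1 cut reproduces that pattern exactly and is the default; the
  underlying rule is not otherwise derivable, so it is configurable and
  not hard-coded anywhere else.
* **Null-vs-real comparison.** Implemented as an independent two-sample
  pooled-variance t-test across subjects per sparsity (real metric vs
  per-subject null mean), matching the "independent two-sample" wording
  of the literature this follows; a paired design would also be
  defensible and can be run by hand from the per-subject tables.
* **BC reliability aggregation.** Whether the per-sparsity ICC of nodal
  BC should be taken over node-mean values or node-by-node is ambiguous;
  `bc_reliability()` emits both, labelled.
* **Proximity measure** for BC-profile similarity matrices: Pearson
  correlation (the default interval-data choice), with cosine and
  Euclidean options.
* **Top-k vs threshold.** Sparsity is defined as an exact edge ratio
  ("the same number of connections for every subject"), so binarization
  keeps exactly the k strongest pairs rather than cutting at a value.

## Known limitations

* Weighted and partial-correlation variants are out of scope (the
  partial-correlation route is ill-posed here anyway: 68 variables
  against 9 samples).
* The shipped Desikan–Killiany centroids are approximate synthetic
  coordinates for visualization export only.
* With 9-feature vectors, per-edge correlation estimates are noisy by
  construction; all conclusions should be read at the level of averaged
  quantities (sweep means, cohort means), which is how the package
  reports them.

## A minimal session

```{r example}
library(morphnet)

cfg <- pipeline_config("out", n_null = 50, seed = 1)
run_all(cfg, synth_config(n_subjects = 20, seed = 1))

read.csv(file.path("out", "reliability.csv"))   # per-sparsity ICCs
read.csv(file.path("out", "hubs.csv"))          # hub stability report
```

Real data enter by pointing `pipeline_config(manifest = ...)` at a CSV
listing `subject_id, session_id, lh_path, rh_path` of FreeSurfer
`?h.aparc.stats` files.
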