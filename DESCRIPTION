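Package: morphnet
Title: Individual Morphological Brain Networks from Multiple Morphometric
    Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construct single-subject morphological brain connectomes by
    correlating standardized multi-feature cortical morphometry vectors
    across the 68 Desikan-Killiany regions, threshold them over a sparsity
    sweep, and analyse the resulting binary graphs: clustering coefficient,
    harmonic-mean characteristic path length, betweenness centrality,
    small-world configurations against degree-preserving null networks,
    and betweenness-based hub identification.  Test-retest reliability of
    features and graph metrics is quantified with one-way random-effects
    intraclass correlation.  A synthetic two-session cohort generator with
    planted modular covariance, planted hubs and a controllable
    between/within-subject variance ratio makes every stage testable
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
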