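Package: engramnet
Title: Brain-Wide Functional Network Analysis of Chemogenetic Memory-Ensemble Reactivation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses brain-wide functional connectivity networks from
    regional BOLD time series recorded during chemogenetic reactivation of tagged
    memory ensembles. Per-animal, per-time-bin Spearman correlation matrices are
    thresholded (Bonferroni-adjusted, positive correlations only) into weighted
    undirected graphs; group consensus networks retain edges significant in a
    configurable fraction of animals. The package computes global efficiency,
    clustering, edge density, eigenvector-centrality hub scores, betweenness and
    closeness with baseline normalisation, detects Louvain communities, scores
    cross-community diversity by Shannon entropy and classifies nodes into the
    connector/provincial hub role taxonomy. Inference uses BCa bootstrap group
    contrasts, degree-preserving rewiring permutation tests on nodal hub-score
    differences, and Pearson hub-behaviour correlations; an in-silico
    disruption-propagation lesion model quantifies each node's impact on global
    efficiency, and a behaviour-seeded minimal network summarises the regions
    linked to task performance. A synthetic-cohort generator with planted
    community structure and hub coupling makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
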