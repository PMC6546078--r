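Package: ecoged
Title: Graph Edit Distance and Information-Theoretic Comparison of Ecological Networks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparing directed consumer-resource (food web) networks.
    Computes graph edit distance between pairs of webs under configurable edit-cost
    schemes (link flip, species add/delete, interaction add/delete), exactly on
    small graphs or by an evolutionary search heuristic on larger ones, and
    normalizes the result to a [0,1] dissimilarity score. Provides Jaccard
    compositional dissimilarity, the interaction beta-diversity partition
    (whole-network, shared-species and turnover components), and adjusted mutual
    information between similarity vectors via equal-frequency discretization and
    the exact hypergeometric expected mutual information. Includes a niche-model
    synthetic food-web generator for communities sampled along a compositional
    gradient with a rewiring knob that decouples interactions from co-occurrence,
    and an orchestration layer that sweeps a grid of 49 cost scenarios over all
    web pairs.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
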