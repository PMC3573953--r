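Package: motudelim
Title: Integrative Molecular Species Delimitation by Minimum Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative molecular species delimitation from
    multi-marker sequence alignments and trees.  Implements per-method
    candidate-species partitions (single-threshold general mixed
    Yule-coalescent fits on ultrametric trees, automatic barcode gap
    discovery over ranked pairwise distances, statistical-parsimony
    haplotype networks under a connection limit, and fixed distance
    threshold clustering), reciprocal-monophyly MOTU extraction from
    gene and concatenated trees, aggregation of Bayesian delimitation
    support tables, and a conservative minimum-consensus rule that
    combines all methods into a secondary species hypothesis.  Includes
    a multispecies-coalescent simulator producing multilocus benchmark
    datasets with known species boundaries and study-like marker
    dropout, so the whole pipeline can be validated by recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    mclust,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
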