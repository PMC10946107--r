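Package: qnetdiff
Title: Differential Rewiring Analysis of Bacterial Co-Occurrence Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds bacterial co-occurrence networks for two sample groups from
    genus-by-sample count tables using compositionally aware (SparCC-style)
    correlation inference, removes false correlations between closely related
    taxa by taxonomy-constrained node contraction after Louvain clustering,
    selects significantly increased core taxa with a one-sided Mann-Whitney U
    test, and ranks taxa by a node-level edge-weighted symmetric-difference
    rewiring index (the QNetDiff score). Includes a synthetic fixture generator
    producing compositional count tables with planted sibling genera,
    differential abundance and rewiring, so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
biocViews: Microbiome, Network, Metagenomics, GraphAndNetwork, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
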