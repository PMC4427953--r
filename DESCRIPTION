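Package: complexRank
Title: Disease-Associated Protein Complex Prioritization on Functional
    Similarity Networks
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds functional similarity networks over protein complexes
    from three sources of evidence (shared subunits, shared Gene Ontology
    annotations with ancestor closure, and shortest-path proximity of
    subunits in a protein-protein interaction network), ranks candidate
    complexes against known disease-associated seed complexes with a
    neighborhood score (NBH) and two network propagation algorithms
    (random walk with restart, RWR; and PRINCE), and evaluates rankings by
    leave-one-out cross-validation with pooled-count ROC curves and AUC.
    Includes a planted-module synthetic data generator so the whole
    pipeline is testable without external databases, plus Welch t-test
    comparisons and a random-set case-study baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
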