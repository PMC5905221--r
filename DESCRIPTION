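Package: dcsMir
Title: Unsupervised miRNA-Disease Association Prediction from a
    Disease-lncRNA-miRNA Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores all disease-miRNA pairs from a tripartite
    disease-lncRNA-miRNA association network without using any known
    miRNA-disease associations. Integrates disease semantic similarity
    over a MeSH-style ontology, Gaussian interaction-profile kernel
    similarities for diseases, lncRNAs and miRNAs, and lncRNA-mediated
    functional similarities, then propagates them through a bounded
    shortest-path ("distance correlation set") scoring scheme. Includes
    a leave-one-out cross-validation ranking harness with ROC/AUC, a
    synthetic tripartite-network generator with planted block signal,
    and TSV readers/writers for association tables and disease
    ontologies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
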