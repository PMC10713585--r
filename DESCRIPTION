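Package: crossorgan
Title: Inter-Organ Disease Mechanism Maps from Multi-Modal Disease Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generative analysis framework for proposing inter-organ disease
    mechanisms from public multi-modal disease-omics resources. A multi-field
    latent Dirichlet allocation model over per-disease gene sets (altered
    expression, biomarker, genetic variation modalities) imputes a missing
    modality for a query disease and, after self- and related-disease
    exclusion, yields latent disease features. These are localized by
    organ/cell-type chi-square enrichment, connected to differentially
    expressed genes through a ligand-receptor pair database, positioned
    upstream or downstream of ligand-receptor pairs by directed KEGG (KGML)
    pathway graph mining, and assembled into an organ-annotated mechanism
    graph. Ships synthetic-data generators with planted structure emulating
    every required input, so the whole pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    MASS,
    igraph,
    jsonlite,
    xml2,
    Rcpp,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mclust,
    DESeq2,
    S4Vectors
Config/testthat/edition: 3
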