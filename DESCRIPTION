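Package: spatialTME
Title: Spatial Niches, Colocalization and Ligand-Receptor Crosstalk in
    Imaging-Based Single-Cell Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for imaging-based single-cell spatial
    transcriptomics of tumor microenvironments: colocalization quotients
    with permutation inference, k-nearest-neighbor neighborhood-composition
    niche detection, proximity-conditioned differential expression,
    range-gated ligand-receptor scoring, per-FOV pseudobulk correlation,
    immune-infiltration stratification, and niche-abundance survival
    analysis, together with a synthetic spatial-cohort generator that
    plants recoverable niches, a sender-receiver expression coupling and
    outcome-linked niche abundance so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    cluster,
    jsonlite,
    methods,
    stats,
    survival,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
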