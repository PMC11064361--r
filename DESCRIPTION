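Package: hic3d
Title: Multiscale Chromatin Architecture Analysis for Two-Condition Hi-C Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of binned chromatin contact maps across scales: Knight-Ruiz
    matrix balancing and quantile normalization, distance-decay expected models,
    stratum-adjusted replicate correlation, Von Neumann entropy of contact
    structure, PC1-based A/B compartment calling with covariate orientation and
    switch detection, directionality-index/HMM TAD calling with insulation-score
    sub-domain partitioning and boundary dynamics, promoter-enhancer interaction
    calling with regulatory potential scores and differential rewiring,
    ROSE-style super-enhancer classification, expression and ortholog
    integration, and a seeded synthetic-data generator with planted
    architectural truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
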