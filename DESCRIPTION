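Package: qhtcp
Title: Quantitative High-Throughput Cell Array Phenotyping and Gene
    Interaction Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative phenomic screens of arrayed spot
    cultures: quantification of time-lapse plate images, logistic
    growth-curve fitting (carrying capacity K, maximum specific rate r,
    time to half capacity L, area under the curve), dose-response gene
    interaction scoring against a replicated single-mutant reference,
    enhancer/suppressor classification with tier ranking and quality
    flags, recursive model-based clustering of interaction profiles with
    hierarchical within-cluster ordering, gene-set enrichment, and a
    seeded synthetic-screen generator with ground truth for validating
    every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    minpack.lm,
    rlang
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    png,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
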