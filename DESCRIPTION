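Package: trioscan
Title: Trio Exome Analysis of Isolated Congenital Heart Defects
Version: 0.1.0
Authors@R:
    person("Trioscan", "Developers", email = "trioscan@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for trio-based exome analysis of isolated
    congenital heart defects (ICHD). Implements post-filtering of somatic
    mosaic candidates, classification of high-quality de novo and inherited
    germline variants with damaging-variant annotation against cardiac gene
    panels, gene constraint and embryonic heart expression, transmission
    disequilibrium testing at the gene and gene-panel level, and a
    CADD-weighted rare-variant burden association test with principal
    component correction for population structure and relatedness exclusion
    from a genetic relationship matrix. Ships a synthetic trio-cohort
    generator with a ground-truth table so that every stage of the cascade
    is testable without access to patient exomes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    jsonlite,
    methods,
    stats,
    SummarizedExperiment,
    tools,
    utils,
    VariantAnnotation
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
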