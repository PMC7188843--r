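Package: PAIscan
Title: Predicting Promoter-Anchored Chromatin Interactions from mQTL
    Summary Statistics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts promoter-anchored chromatin interactions (PAIs)
    between DNA methylation sites from cis-mQTL summary statistics using
    summary-data-based Mendelian randomisation (SMR) with the HEIDI
    heterogeneity test and an LD-aware covariance of instrument ratio
    estimates. Includes distance- and variance-matched resampling
    enrichment analyses of the predicted interactions against chromatin
    annotations (TADs, loops, chromatin states, ChIP peaks, eQTLs, gene
    expression), cross-tissue replication summaries with an
    error-corrected effect-correlation (rb) estimator, and a
    synthetic-data generator for calibration and power experiments on
    LD-structured genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
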