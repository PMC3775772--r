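Package: ctrlscreen
Title: Screening and Validation of Stable Endogenous Control Genes from
    Multi-Dataset RNA-seq Expression Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies maximally consistent endogenous control genes for
    qRT-PCR normalization from gene-by-sample RPKM expression matrices.
    Implements per-gene stability statistics (mean RPKM, coefficient of
    variation, maximum fold change), ranking and panel summaries, rolling
    window CV quantile curves across the transcriptome, stratified candidate
    selection under CV/MFC thresholds, cross-dataset criterion scoring,
    GeNorm expression-consistency M values, and delta-delta-Ct relative
    quantification with Spearman RPKM-to-dCt validation statistics. A
    synthetic-data generator produces multi-cohort RPKM matrices with
    planted stable and variable genes plus matched qPCR Ct tables so the
    whole screen is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
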