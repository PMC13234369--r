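Package: pathstrat
Title: Pathway Activity Scores, Co-Expression Signatures and
    Optimal-Cutpoint Survival Stratification for Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the transcriptome arm of tumor-metabolism studies:
    single-sample pathway activity scoring as the oriented first principal
    component of z-scored log2 expression of a gene set, anchor-gene
    co-expression signatures with a Pearson-threshold membership rule,
    fold-change pre-ranking for enrichment tools, tumor-versus-normal and
    score-versus-score statistics with regression confidence bands,
    Kaplan-Meier estimation with minimum-p log-rank cutpoint stratification
    (including a permutation correction for cutoff-selection bias) and
    two-marker 2x2 survival stratification, an ROI-masked fluorescence
    co-localization percentage, and a latent-factor synthetic-data
    generator so that every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
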