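Package: regdir
Title: Direction-Aware Regulon and Gene-Set Activity Analysis for
    Bacterial Transcriptomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gene-set enrichment analysis of differential-expression
    tables that accounts for the directionality of transcriptional
    regulation. Regulons are split into groups consistent with an
    activated or a repressed regulator, the majority group determines a
    signed regulator-activity score, its dispersion (median absolute
    deviation) and the logical-regulation fraction, and significance is
    assessed with a weighted Kolmogorov-Smirnov enrichment score and
    gene-label permutation P-values under Benjamini-Hochberg FDR
    control. Also scores hierarchical functional categories, reports
    per-gene regulon candidates, screens operons for internally
    discordant expression, generates synthetic benchmark tables with
    planted ground truth, and draws bubble, volcano and spread plots
    with companion data tables.
License: MIT
Encoding: UTF-8
Imports:
    ggplot2,
    methods,
    stats,
    tools,
    utils
Suggests:
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
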