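Package: retromethyl
Title: Retroelement Locus Expression, Consensus Calling and Methylation Coupling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of locus-specific endogenous retrovirus
    (HERV-K HML-2) expression in tumor/normal comparisons. Provides
    cross-tool concordance statistics (Pearson correlation and Cohen's
    kappa on categorized differential-expression calls) with consensus
    locus selection, genomic association of retroelement loci with host
    and flanking genes, CpG methylation-expression coupling via windowed
    pairing, effect-size and significance filtering, Spearman correlation
    and strand/promoter interaction regressions, and delta-delta-Ct qPCR
    summarization. A synthetic-data module generates all input classes
    with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
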