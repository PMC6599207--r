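Package: oncohistoneScreen
Title: Oncohistone Screening and Spike-In ChIP Quantification for AML Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for histone H3 mutation screening in acute
    myeloid leukemia cohorts: variant retention and caller-consensus filters,
    variant-allele-frequency clonality classification against remission
    samples, exact Fisher enrichment statistics over cohort contingency
    tables, spike-in (ChIP-Rx) normalized promoter H3K27me3/H3K27ac
    quantification with input subtraction and replicate averaging, a
    z-score differential statistic for ChIP and triplicate RNA abundance,
    Tukey box/notch summaries of promoter-set shifts, an exact Mann-Whitney
    test for xenograft engraftment, and a synthetic-data generator that
    emulates the cohort, read-level and expression structure the pipeline
    assumes so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
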