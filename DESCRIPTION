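Package: adaptscape
Title: Landscape Genomics Scans for Environmental Adaptation in Crop Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A covariance-aware landscape-genomics toolkit for genebank
    germplasm panels of selfing crops. Estimates the allele-frequency
    covariance matrix among populations, scans biallelic SNPs for excess
    differentiation (XtX) and for association with environmental covariates
    via closed-form Bayes factors in deciban units, calibrates significance
    with pseudo-observed data, merges significant SNPs into adaptation
    signatures, analyses linkage-disequilibrium networks among signature
    peaks, compares haplotype-block frequencies across germplasm groups, and
    annotates candidate regions with gene models and GO enrichment.
    Environmental covariates are derived from monthly climate summaries over
    cultivation regions and summarized by principal component analysis. A
    built-in synthetic-data generator with a truth ledger makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    igraph,
    ape,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
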