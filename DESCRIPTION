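Package: hybzone
Title: Replicated Hybrid-Zone Analysis of Introgression and Local Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing replicated hybrid zones from SNP genotype
    matrices: maximum-likelihood hybrid-index estimation against parental
    allele-frequency panels, per-SNP Weir-Cockerham FST and missing-data-aware
    pi/dxy, genotype-environment association scans driven by a redundancy-
    analysis composite predictor, Bayesian genomic-cline (alpha/beta) inference
    by MCMC with equal-tail-interval outlier calls, linkage-map super-scaffold
    anchoring with ordinal Moran's I autocorrelation comparisons, and
    candidate-gene overlap enrichment. Includes a hybrid-zone simulator with
    known truth so every stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
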