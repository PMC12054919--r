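Package: lactovar
Title: Functional-Class Variance Partitioning and Genomic Prediction for
    Milk Production Traits
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for dissecting the genetic architecture of milk
    production traits with mammary multi-omics functional classes.
    Implements genotype quality control and VanRaden genomic relationship
    matrices, multi-GRM average-information REML variance partitioning
    with per-class enrichment odds ratios and a circular genome-shift
    permutation null, tissue-specificity t-statistics, miRNA target
    anti-correlation enrichment and prioritization, hyper-editing style
    A-to-I RNA editing detection with cluster calling and stage
    comparison, and functional-class-informed genomic prediction (GBLUP,
    MultiBLUP, BayesR and BayesRC with four-component normal mixture
    priors).  A synthetic-data generator with recorded ground truth makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
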