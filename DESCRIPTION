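Package: hiscompca
Title: Hierarchical Structural Component Models for Pathway Analysis of
    Common Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pathway-level association testing for genome-wide association
    studies of common variants (HisCoM-PCA). SNP dosages are summarized to
    per-gene principal components, and all pathways are analyzed jointly in a
    single hierarchical structural component generalized linear model with
    ridge penalties on the gene-weight and pathway-effect layers, fitted by
    alternating least squares. Inference for pathway and gene effects uses
    phenotype-permutation null distributions with Benjamini-Hochberg false
    discovery rate control, and penalty parameters are tuned by k-fold
    cross-validation. Includes readers for PLINK binary genotypes, GMT gene
    sets and phenotype tables, quality-control filters (minor allele
    frequency, call rate, exact Hardy-Weinberg test), and a pathway-structured
    genotype/phenotype simulator for power and type-I-error experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
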