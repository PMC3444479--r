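Package: mtTreeScan
Title: Haplotype-Network Association Scanning for Mitochondrial
    Case-Control Cohorts
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for evolution-based association analysis of full
    mitochondrial genomes in case-control cohorts. Builds statistical
    parsimony haplotype networks from per-subject variant tables, tests
    every branch-induced bi-allelic partition of the network with
    Firth-penalized logistic regression and covariates, corrects across
    the correlated branch family by step-down minP permutation, and
    supports conditional second-round scans. Includes pedigree kinship
    and familial-risk covariates, matrilineal haplotype imputation, and
    a fully synthetic cohort generator (coalescent haplotypes,
    matrilineal pedigrees, covariates, planted protective clades) so the
    whole pipeline is testable without access to protected cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    ape,
    Biostrings,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'mtTreeScan-package.R'
    'AllGenerics.R'
    'RcppExports.R'
    'reference.R'
    'variants.R'
    'haplotypes.R'
    'network.R'
    'partitions.R'
    'treescan.R'
    'pedigree.R'
    'simulate.R'
    'pipeline.R'
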