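Package: bfawm
Title: Bayes Factor Association Weight Matrix Networks from Whole-Genome
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for regulatory gene-network inference from
    multi-trait genomic data in livestock populations. Fits a weighted
    BayesB whole-genome regression by Gibbs sampling to obtain per-marker
    posterior effects and model frequencies, converts model frequencies to
    Bayes factors with suggestive/strong/decisive evidence classes,
    summarises genetic variance over non-overlapping 1-Mb genome windows,
    builds an association weight matrix (AWM) of z-normalised additive
    effects with one representative SNP per gene, infers a co-association
    network with the partial correlation and information theory (PCIT)
    algorithm, and validates the network in silico by position-weight-matrix
    promoter scanning with exact p-values and maximum-coverage selection of
    a transcription-factor trio. Includes a simulator that generates
    LD-structured genotypes, heritability-controlled deregressed breeding
    values, gene annotation, and promoters with planted motif occurrences,
    so the whole pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
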