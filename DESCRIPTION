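Package: popgenpanel
Title: Diversity and Population Structure Analysis for SNP Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genetic characterisation of crop germplasm panels
    genotyped with biallelic SNP markers, with defaults tuned to inbred
    (selfing) cereal collections such as bread wheat.  Covers marker quality
    control (missingness and minor-allele-frequency filters, polymorphism
    partition between germplasm groups, LD-based marker thinning), Nei gene
    diversity statistics (PIC, H_T, H_S, D_ST, G_ST) and gene-flow estimates
    (Nm), intra-chromosomal linkage disequilibrium scans with LOESS decay
    estimation, a Gibbs-sampler implementation of the Bayesian admixture model
    with Evanno delta-K model selection, simple-matching distances with
    neighbour-joining trees and principal coordinates analysis, and a
    structured-panel simulator (Balding-Nichols F-model with Dirichlet
    admixture, selfing and along-chromosome linkage) providing ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
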