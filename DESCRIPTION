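Package: bulkpop
Title: Population Genetics of Bulked Microsatellite Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of simple sequence repeat (SSR) genotyping of population
    bulks, in which pooled DNA from many plants is run as a single sample and
    allele frequencies are inferred from relative electropherogram peak
    intensities. Provides peak binning with stutter and noise filtering,
    pooled allele-frequency estimation, simulation of diploid
    pseudo-individuals matching bulk frequencies and expected heterozygosity,
    Nei gene diversity and unique-allele summaries, proportion-of-shared-
    alleles distances with neighbor-joining trees and principal coordinate
    analysis, a Bayesian admixture model fitted by Gibbs sampling with
    Evanno delta-K model selection, ancestry-threshold group assignment and
    hierarchical sub-structure analysis, and a fully seeded synthetic-data
    generator for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
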