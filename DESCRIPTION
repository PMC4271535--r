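Package: pedmutr
Title: De Novo Mutation Rate Estimation from Parent-Offspring Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating the spontaneous mutation rate from
    whole-genome sequencing of two parents and their offspring, designed
    around the study design used for butterflies and other organisms with
    draft genome assemblies: deeply sequenced "focal" offspring in which
    de novo heterozygotes are called, and shallowly sequenced "bait"
    siblings used to screen out paralog-mismapping artifacts.  Includes a
    seeded simulator of pedigree sequencing read counts, a multi-sample
    biallelic genotype caller, the six-rule candidate filter, empirical
    heterozygote allele-depth distributions built from chromosome-wide
    maternal segregation patterns, synthetic-mutation spike-in calibration
    of callability and false-negative rates, and downstream arithmetic for
    rates with exact Poisson confidence intervals, effective population
    size and divergence dates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
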