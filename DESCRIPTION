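Package: stratpg
Title: Population-Genetic Diversity, Scenario-Choice ABC and Time-Stratified
    Dispersal Models for Multi-Locus Phylogeography
Version: 0.1.0
Authors@R: person("stratpg", "developers", email = "stratpg@example.org",
    role = c("aut", "cre"))
Description: Tools for phylogeographic analyses that combine mitochondrial
    sequence alignments and diploid microsatellite genotypes sampled from a
    set of geographic populations. Provides haplotype and nucleotide
    diversity, Tajima's D and Fu's Fs neutrality tests with coalescent
    p-values, Tamura (1992) gamma-corrected distances, AMOVA-based FST and
    PhiST with permutation tests and Benjamini-Yekutieli FDR correction,
    microsatellite diversity and differentiation (bias-corrected GST,
    Hedrick's standardized G'ST, Jost's D), Goldstein's (delta-mu)^2
    distance, heterozygosity-excess bottleneck tests, and principal
    coordinates analysis. A structured-coalescent simulator of event-based
    divergence/admixture scenarios generates joint mtDNA (HKY+G) and
    microsatellite (generalized stepwise) datasets and feeds an approximate
    Bayesian computation module for scenario choice by the direct k-nearest
    neighbour estimator. A dispersal-extinction-cladogenesis module fits
    DEC, DIVALIKE and BAYAREALIKE models (with and without founder-event
    jumps) on dated ultrametric trees under time-stratified dispersal
    multiplier matrices and compares dispersal hypotheses by AIC/AICc
    weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    Matrix
Config/testthat/edition: 3
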