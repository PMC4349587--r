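Package: hybridzone
Title: Hybrid Zone Analysis of Codominant Microsatellite Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing plant hybrid zones from diploid
    codominant multilocus genotypes (microsatellites). Provides a genotype
    container with STRUCTURE and GenePop text I/O; diversity and
    differentiation statistics (allelic richness, observed and expected
    heterozygosity, Weir-Cockerham F_IS and pairwise F_ST with permutation
    tests); individual-level Nei D_A distances with principal coordinates
    ordination; Hartigan's dip test of admixture-proportion modality; a
    Bayesian admixture model (Gibbs sampler with independent allele
    frequencies, Evanno delta-K model choice and replicate alignment); a
    six-category genealogical-class mixture model (pure parents, F1, F2 and
    first-generation backcrosses); a composite classification pipeline with
    later-generation fallback rules; and a hybrid-genotype simulator
    (Balding-Nichols parental pools plus gamete-level hybrid classes) used
    for power evaluation of the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
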