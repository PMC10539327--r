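Package: dispersim
Title: Agent-Based Simulation of the Genetic Architecture of Insect Dispersal
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-based quantitative-genetic simulation of artificial
    selection on dispersal behaviour in flour beetles (Tribolium castaneum),
    and of the follow-up experiments used to probe the genetic architecture of
    the trait: reciprocal crosses between selected lines and extreme inbreeding
    through repeated sib mating.  Dispersal is modelled as a threshold-like
    binary behaviour controlled by 1, 3, 5 or 10 additive biallelic loci
    (autosomal, or X-linked in the single-locus case) with configurable
    dominance, heritability and founding allele frequency.  The package also
    provides the evaluation layer that turns simulations into architectural
    inference: scoring simulated selection trajectories against a published
    fixed-effect model of the experimental response, sex-bias metrics,
    fixed-effect linear models for simulated cross assays, and Hartigan's dip
    statistic with Monte Carlo p-values for multimodality testing of inbred
    line phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
RoxygenNote: 7.3.3
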