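Package: grainfill
Title: Gamma-Mixture Description of Rice Grain Weight Distributions and
    Genomic Prediction of Grain-Filling Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Describes single-grain weight distributions of rice cultivars as
    two-component gamma mixtures fitted by a multi-restart EM algorithm with
    Minka's fixed-point gamma maximum-likelihood updates.  Derives
    interpretable grain-filling statistics (component modes, moments, the
    boundary point between unfilled and filled grains) and conventional
    grain-filling traits, computes a closed-form squared-L2 distance between
    mixture densities (PRESS and the shape-level Q2 skill score), and
    predicts the genotype-specific mixture parameters from genome-wide
    biallelic markers via GBLUP with REML variance components and grouped
    multi-response partial least squares, evaluated by leave-one-out
    cross-validation.  Includes a synthetic-data generator for inbred marker
    panels, additively heritable mixture parameters, and grain-weight
    samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    vcfR,
    optparse
Config/testthat/edition: 3
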