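Package: dispersim
Title: Simulated Disperser Analysis for Marker Panel Power
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating genetic assignment tests used to detect
    first-generation dispersers from co-dominant multi-locus genotypes.
    Implements partial-Bayesian (Rannala-Mountain) assignment likelihoods
    with Monte Carlo Lh/Lmax p-values, per-locus statistics (polymorphic
    information content, Weir-Cockerham theta, Shannon mutual information,
    Hardy-Weinberg screening), and Simulated Disperser Analysis: relabelling
    sampled individuals into other populations and re-running detection over
    nested PIC-ranked locus panels to measure how many markers a study
    system needs. Includes a Balding-Nichols synthetic genotype generator,
    GENEPOP and tabular I/O, and logistic power models of correct
    identification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
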