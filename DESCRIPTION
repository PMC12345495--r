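Package: POHselect
Title: Mate Selection and Forward Simulation by Probability of Offspring
    Heterozygosity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conservation-breeding toolkit that scores candidate sire x dam
    pairs by the probability that their offspring are heterozygous (POH) at a
    panel of unlinked biallelic SNPs, seats a requested number of disjoint
    breeding pairs under littermate and monogamy constraints, and simulates
    the resulting populations forward in time under Mendelian segregation.
    Includes allele-sharing (ASp) and random mate selection as comparators,
    observed and expected heterozygosity trajectory tracking with replicate
    averaging and exponentially weighted smoothing, a linked-locus mode with
    per-locus recombination fractions for studying unselected passenger loci,
    a synthetic founder-cohort generator, and a command-line interface for
    running simulation experiments and producing ranked mating plans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
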