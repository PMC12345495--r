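# Independent oracles used across the suite.

# alleles carried by a dosage genotype
allelesOf <- function(g) switch(as.character(g),
    "0" = c(0L, 0L), "1" = c(0L, 1L), "2" = c(1L, 1L))

# Exhaustive 4-gamete enumeration: distribution of offspring dosages for a
# parental genotype pair (each parental allele transmitted with prob 1/4).
offspringDistOracle <- function(g1, g2) {
    combos <- outer(allelesOf(g1), allelesOf(g2), "+")
    p <- tabulate(as.vector(combos) + 1L, nbins = 3L) / 4
    names(p) <- c("0", "1", "2")
    p
}

# probability the offspring is heterozygous, by enumeration
pohOracle <- function(g1, g2) offspringDistOracle(g1, g2)[["1"]]

# small deterministic population builder
toyPopulation <- function(maleGenos, femaleGenos, litterM = NULL,
                          litterF = NULL) {
    g <- rbind(do.call(rbind, lapply(maleGenos, rbind)),
               do.call(rbind, lapply(femaleGenos, rbind)))
    nm <- length(maleGenos)
    nf <- length(femaleGenos)
    litter <- c(if (is.null(litterM)) paste0("m", seq_len(nm)) else litterM,
                if (is.null(litterF)) paste0("f", seq_len(nf)) else litterF)
    Population(g, c(rep("M", nm), rep("F", nf)), litter = litter)
}

# max achievable score among eligible candidates not touching used individuals
bestRemainingScore <- function(pop, usedM, usedF, metric) {
    cand <- eligiblePairs(pop)
    g <- genotypes(pop)
    best <- NULL
    for (i in seq_len(nrow(cand))) {
        m <- cand$male[i]; f <- cand$female[i]
        if (m %in% usedM || f %in% usedF) next
        best <- c(best, pairScore(g[m, ], g[f, ], metric))
    }
    best
}
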