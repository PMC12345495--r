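# Frozen single-locus score table: rows g1, g2, POH, ASp, ASp 0-1
SCORE_TABLE <- rbind(
    c(0, 0, 0.0, 0.50, 1.0),
    c(0, 1, 0.5, 0.25, 0.5),
    c(0, 2, 1.0, 0.00, 0.0),
    c(1, 0, 0.5, 0.25, 0.5),
    c(1, 1, 0.5, 0.50, 1.0),
    c(1, 2, 0.5, 0.25, 0.5),
    c(2, 0, 1.0, 0.00, 0.0),
    c(2, 1, 0.5, 0.25, 0.5),
    c(2, 2, 0.0, 0.50, 1.0))

test_that("all nine genotype pairs reproduce the POH/ASp score table", {
    for (i in seq_len(nrow(SCORE_TABLE))) {
        g1 <- SCORE_TABLE[i, 1]; g2 <- SCORE_TABLE[i, 2]
        expect_equal(pohLocus(g1, g2), SCORE_TABLE[i, 3])
        expect_equal(aspLocus(g1, g2), SCORE_TABLE[i, 4])
        expect_equal(aspScaled(g1, g2), SCORE_TABLE[i, 5])
    }
    expect_error(pohLocus(3, 0), "0, 1 or 2")
    expect_error(aspLocus(0, -1), "0, 1 or 2")
})

test_that("POH equals the exhaustive four-gamete heterozygosity fraction", {
    for (g1 in 0:2) for (g2 in 0:2) {
        expect_equal(pohLocus(g1, g2), pohOracle(g1, g2))
        expect_equal(pohLocus(g1, g2), pohLocus(g2, g1))
        expect_equal(aspLocus(g1, g2), aspLocus(g2, g1))
    }
})

test_that("POH complements scaled ASp except for double heterozygotes", {
    for (g1 in 0:2) for (g2 in 0:2) {
        if (g1 == 1 && g2 == 1) {
            expect_equal(pohLocus(1, 1), 0.5)
            expect_equal(aspScaled(1, 1), 1)
        } else {
            expect_equal(pohLocus(g1, g2), 1 - aspScaled(g1, g2))
        }
    }
})

test_that("multi-locus pair scores average per-locus values", {
    expect_equal(pairScore(c(0, 1), c(2, 1), "POH"), 0.75)
    expect_equal(pairScore(c(0, 0), c(0, 2), "ASp"), 0.25)
    expect_equal(pairScore(c(0, 2, 0), c(0, 2, 0), "POH"), 0)
    expect_error(pairScore(c(0, 1), 2), "same length")
    expect_error(pairScore(integer(0), integer(0)), "at least one locus")

    set.seed(5)
    for (rep in 1:20) {
        L <- sample(1:12, 1)
        a <- sample(0:2, L, replace = TRUE)
        b <- sample(0:2, L, replace = TRUE)
        perm <- sample(L)
        for (m in c("POH", "ASp")) {
            expect_equal(pairScore(a, b, m), pairScore(b, a, m))
            expect_equal(pairScore(a[perm], b[perm], m), pairScore(a, b, m))
        }
    }
})

test_that("matrix cross-scoring agrees with per-pair averaging", {
    set.seed(8)
    Gm <- matrix(sample(0:2, 5 * 7, replace = TRUE), 5, 7)
    Gf <- matrix(sample(0:2, 4 * 7, replace = TRUE), 4, 7)
    for (m in c("POH", "ASp")) {
        S <- POHselect:::.scoreCross(Gm, Gf, m)
        for (i in 1:5) for (j in 1:4)
            expect_equal(S[i, j], pairScore(Gm[i, ], Gf[j, ], m))
    }
})

test_that("eligible pairs exclude littermates", {
    pop <- toyPopulation(list(0, 1), list(2, 1))
    expect_equal(nrow(eligiblePairs(pop)), 4L)

    pop2 <- toyPopulation(list(0, 1), list(2, 1),
                          litterM = c("A", "x"), litterF = c("A", "y"))
    expect_equal(nrow(eligiblePairs(pop2)), 3L)

    pop3 <- toyPopulation(list(0, 1), list(2, 1),
                          litterM = c("A", "A"), litterF = c("A", "A"))
    expect_equal(nrow(eligiblePairs(pop3)), 0L)
})

test_that("mating plans rank eligible pairs and write TSV", {
    pop <- toyPopulation(list(c(0, 0), c(1, 1)), list(c(2, 2), c(0, 2)))
    plan <- matingPlan(pop, rankBy = "POH")
    expect_equal(nrow(plan), 4L)
    expect_equal(plan$POH[1], 1)  # AA,AA x BB,BB tops the list
    expect_true(all(diff(plan$POH) <= 0))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeMatingPlan(plan, path)
    back <- read.delim(path)
    expect_equal(back$POH, plan$POH)

    lonely <- toyPopulation(list(0), list(2), litterM = "A", litterF = "A")
    expect_warning(empty <- matingPlan(lonely), "no eligible")
    expect_equal(nrow(empty), 0L)
})
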