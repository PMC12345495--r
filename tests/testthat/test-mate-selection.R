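test_that("a single opposite-homozygote pair is seated with score 1", {
    pop <- toyPopulation(list(0), list(2))
    set.seed(1)
    out <- selectPairs(pop, 1, "POH")
    expect_s4_class(out, "SelectionOutcome")
    expect_equal(nrow(selectedPairs(out)), 1L)
    expect_equal(out@meanPairScore, 1)
    expect_equal(meanPairPOH(out), 1)
})

test_that("selection is deterministic given population, mode and seed", {
    pop <- Population(matrix(sample(0:2, 80, replace = TRUE), 16, 5),
                      rep(c("M", "F"), each = 8))
    for (mode in c("POH", "ASp", "random")) {
        set.seed(42); a <- selectPairs(pop, 5, mode)
        set.seed(42); b <- selectPairs(pop, 5, mode)
        expect_identical(selectedPairs(a), selectedPairs(b))
    }
})

test_that("greedy seating matches the exhaustive best-remaining oracle", {
    set.seed(7)
    for (rep in 1:10) {
        pop <- Population(matrix(sample(0:2, 8, replace = TRUE), 8, 1),
                          rep(c("M", "F"), each = 4))
        for (mode in c("POH", "ASp")) {
            set.seed(100 + rep)
            out <- selectPairs(pop, 3, mode)
            p <- selectedPairs(out)
            usedM <- integer(0); usedF <- integer(0)
            for (i in seq_len(nrow(p))) {
                rem <- bestRemainingScore(pop, usedM, usedF, mode)
                target <- if (mode == "POH") max(rem) else min(rem)
                expect_equal(p$score[i], target)
                usedM <- c(usedM, p$male[i]); usedF <- c(usedF, p$female[i])
            }
        }
    }
})

test_that("the first POH pair always attains the global maximum score", {
    set.seed(21)
    for (rep in 1:10) {
        pop <- Population(matrix(sample(0:2, 36, replace = TRUE), 12, 3),
                          rep(c("M", "F"), each = 6))
        out <- selectPairs(pop, 4, "POH")
        cand <- eligiblePairs(pop)
        g <- genotypes(pop)
        allScores <- mapply(function(m, f) pairScore(g[m, ], g[f, ], "POH"),
                            cand$male, cand$female)
        expect_equal(selectedPairs(out)$score[1], max(allScores))
    }
})

test_that("infeasible requests report the achievable pair count", {
    # m1 is littermate of both females: only m2 can be seated
    pop <- toyPopulation(list(0, 1), list(2, 1),
                         litterM = c("A", "B"), litterF = c("A", "A"))
    err <- tryCatch(selectPairs(pop, 2, "POH"), error = identity)
    expect_s3_class(err, "infeasibleSelection")
    expect_match(conditionMessage(err), "only 1 achievable")
    expect_equal(err$achievable, 1L)

    all.sibs <- toyPopulation(list(0, 1), list(2, 1),
                              litterM = c("A", "A"), litterF = c("A", "A"))
    err2 <- tryCatch(selectPairs(all.sibs, 1, "POH"), error = identity)
    expect_s3_class(err2, "infeasibleSelection")
    expect_equal(err2$achievable, 0L)
})

test_that("no individual is seated twice and monogamy holds at full load", {
    pop <- Population(matrix(sample(0:2, 40, replace = TRUE), 20, 2),
                      rep(c("M", "F"), each = 10))
    set.seed(3)
    out <- selectPairs(pop, 10, "POH")
    p <- selectedPairs(out)
    expect_equal(anyDuplicated(c(p$male, p$female)), 0L)
    expect_equal(nrow(p), 10L)
})

test_that("random mode is seed-reproducible and covers all seatings", {
    pop <- toyPopulation(list(0, 1), list(2, 1))
    set.seed(9); a <- selectedPairs(selectPairs(pop, 2, "random"))
    set.seed(9); b <- selectedPairs(selectPairs(pop, 2, "random"))
    expect_identical(a, b)
    # 2M x 2F admit exactly two disjoint 2-pair seatings; both must occur
    seatings <- character(0)
    for (s in 1:40) {
        set.seed(s)
        p <- selectedPairs(selectPairs(pop, 2, "random"))
        p <- p[order(p$male), ]
        seatings <- c(seatings, paste(p$female, collapse = "-"))
    }
    expect_setequal(unique(seatings), c("3-4", "4-3"))
})
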