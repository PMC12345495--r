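test_that("condition tags parse and render round-trip", {
    cond <- parseCondition("M51-BP10-Li4-Ge50")
    expect_equal(c(cond@M, cond@BP, cond@Li, cond@Ge), c(51L, 10L, 4L, 50L))
    expect_equal(conditionTag(cond), "M51-BP10-Li4-Ge50")
    cond2 <- parseCondition("M1-BP3-Li4-Ge50", mode = "ASp", seed = 9)
    expect_equal(c(cond2@M, cond2@BP), c(1L, 3L))
    expect_equal(cond2@mode, "ASp")
    expect_error(parseCondition("M51-BPx-Li4-Ge50"), "BP field")
    expect_error(parseCondition("M51-BP10-Li4"), "four fields")
    expect_error(parseCondition("X51-BP10-Li4-Ge50"), "M field")
    expect_error(SimCondition(1, 3, 4, 50, mode = "best"), "mode")
    expect_error(SimCondition(0, 3, 4, 50), "M")
})

test_that("one generation step produces exactly BP x Li offspring", {
    base <- synthesizeBase(seed = 7)
    set.seed(7)
    res <- runGeneration(base, SimCondition(51, 10, 4, 1))
    expect_equal(nIndividuals(res$population), 40L)
    expect_equal(generationIndex(res$population), 1L)
    expect_equal(length(unique(litters(res$population))), 10L)
    # non-overlap: offspring litter ids are disjoint from founder ids
    expect_length(intersect(litters(res$population), litters(base)), 0)
})

test_that("an all-heterozygote generation caps pair POH at 0.5", {
    pop <- Population(matrix(1L, 12, 1), rep(c("M", "F"), each = 6),
                      litter = rep(c("a", "b", "c"), 4))
    set.seed(5)
    res <- runGeneration(pop, SimCondition(1, 3, 4, 1))
    expect_equal(res$stats[["meanPairPOH"]], 0.5)
})

test_that("trajectories are seed-deterministic and include generation 0", {
    base <- synthesizeBase(seed = 3)
    cond <- SimCondition(51, 5, 4, 10, "POH", seed = 11)
    a <- runSimulation(base, cond)
    b <- runSimulation(base, cond)
    expect_identical(a, b)
    expect_equal(a$generation, 0:10)
    expect_equal(a$hObs[1], hObs(base))
    expect_equal(a$hExp[1], hExp(base))
    expect_true(is.na(a$meanPairPOH[1]))
    expect_false(attr(a, "truncated"))
    # Ge = 1 reduces to a single runGeneration step
    one <- runSimulation(base, SimCondition(51, 5, 4, 1, seed = 11))
    expect_equal(one[2, c("hObs", "hExp")], a[2, c("hObs", "hExp")])
})

test_that("infeasible generations truncate the trajectory with a flag", {
    # a base that is one single litter: no eligible pair at all
    pop <- Population(matrix(1L, 4, 1), c("M", "M", "F", "F"),
                      litter = rep("one", 4))
    tr <- runSimulation(pop, SimCondition(1, 1, 4, 5, seed = 2))
    expect_true(attr(tr, "truncated"))
    expect_equal(nrow(tr), 1L)  # only generation 0 recorded
})

test_that("fixation is not an error: selection ties at zero and continues", {
    pop <- Population(matrix(c(0L, 2L), 8, 1), rep(c("M", "F"), each = 4),
                      litter = paste0("l", 1:8))
    pop@genotypes[] <- 0L  # all loci fixed for allele A
    tr <- runSimulation(pop, SimCondition(1, 2, 4, 8, seed = 4))
    expect_false(attr(tr, "truncated"))
    expect_equal(nrow(tr), 9L)
    expect_true(all(tr$hObs == 0))
})

test_that("replicates aggregate to the per-generation arithmetic mean", {
    base <- synthesizeBase(10, 10, nLoci = 5, seed = 8)
    cond <- SimCondition(5, 3, 4, 6, "POH", seed = 20)
    res <- runReplicates(base, cond, 4)
    reps <- trajectories(res)
    expect_length(reps, 4L)
    expect_true(all(vapply(reps, nrow, 1L) == 7L))
    agg <- aggregated(res)
    for (g in 0:6) {
        expect_equal(agg$hObs[g + 1],
                     mean(vapply(reps, function(d) d$hObs[g + 1], 1)))
    }
    # replicate r is the plain single run at seed + r
    solo <- runSimulation(base, initialize(cond, seed = cond@seed + 2L))
    expect_identical(reps[[2]], solo)
    # n = 1: aggregate equals the single trajectory
    res1 <- runReplicates(base, cond, 1)
    expect_equal(aggregated(res1)$hObs, trajectories(res1)[[1]]$hObs)
})

test_that("single-marker POH runs oscillate: peaks at 1 must fall back", {
    base <- synthesizeBase(nLoci = 1, seed = 5)
    tr <- runSimulation(base, SimCondition(1, 3, 4, 50, seed = 5))
    hit <- which(tr$hObs == 1)
    hit <- hit[hit < nrow(tr)]
    expect_gt(length(hit), 0)
    expect_true(all(tr$hObs[hit + 1] < 1))
    expect_true(all(tr$hObs > 0))  # POH keeps the marker segregating here
})

test_that("trajectory TSVs carry replicate labels and the aggregate", {
    base <- synthesizeBase(6, 6, nLoci = 3, seed = 2)
    res <- runReplicates(base, SimCondition(3, 2, 4, 3, seed = 1), 2)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeTrajectory(res, path)
    tab <- read.delim(path)
    expect_setequal(unique(tab$replicate), c("1", "2", "mean"))
    expect_equal(nrow(tab), 3 * 4)
})
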