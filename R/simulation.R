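#' Construct a simulation condition
#'
#' @param M marker count scored per pair (for linked mode, the single focal
#'   locus; passengers are never scored).
#' @param BP breeding pairs seated per generation.
#' @param Li litter size; each generation consists of exactly BP x Li
#'   offspring (generations do not overlap).
#' @param Ge number of generations to simulate.
#' @param mode selection mode: \code{"POH"}, \code{"ASp"} or \code{"random"}.
#' @param seed base seed of the random stream; replicate r of
#'   [runReplicates()] uses \code{seed + r}.
#' @param r recombination fractions of passenger loci (linked mode); empty
#'   for the default unlinked simulation.
#' @return a [SimCondition-class].
#' @examples
#' SimCondition(51, 10, 4, 50)
#' @export
SimCondition <- function(M, BP, Li, Ge, mode = "POH", seed = 1L,
                         r = numeric(0)) {
    new("SimCondition", M = as.integer(M), BP = as.integer(BP),
        Li = as.integer(Li), Ge = as.integer(Ge), mode = mode,
        seed = as.integer(seed), r = as.numeric(r))
}

#' Parse a parameter-condition tag
#'
#' Conditions are abbreviated as \code{"M<m>-BP<bp>-Li<li>-Ge<ge>"}, e.g.
#' \code{"M51-BP10-Li4-Ge50"} for 51 markers, 10 breeding pairs, litters of
#' four, 50 generations.
#'
#' @param tag condition tag string.
#' @param mode,seed,r passed through to [SimCondition()].
#' @return a [SimCondition-class].
#' @examples
#' parseCondition("M51-BP10-Li4-Ge50")
#' @export
parseCondition <- function(tag, mode = "POH", seed = 1L, r = numeric(0)) {
    if (length(tag) != 1L || !is.character(tag))
        stop("condition tag must be a single string")
    parts <- strsplit(tag, "-", fixed = TRUE)[[1]]
    prefixes <- c("M", "BP", "Li", "Ge")
    if (length(parts) != 4L)
        stop("condition tag must have four fields M<int>-BP<int>-Li<int>-Ge<int>")
    vals <- integer(4)
    for (i in seq_along(prefixes)) {
        if (!grepl(sprintf("^%s[0-9]+$", prefixes[i]), parts[i]))
            stop(sprintf("malformed %s field in condition tag: '%s'",
                         prefixes[i], parts[i]))
        vals[i] <- as.integer(sub(prefixes[i], "", parts[i], fixed = TRUE))
    }
    SimCondition(vals[1], vals[2], vals[3], vals[4], mode = mode, seed = seed,
                 r = r)
}

#' @param cond a [SimCondition-class].
#' @rdname parseCondition
#' @export
conditionTag <- function(cond) {
    sprintf("M%d-BP%d-Li%d-Ge%d", cond@M, cond@BP, cond@Li, cond@Ge)
}

#' @export
setMethod("show", "SimCondition", function(object) {
    cat(sprintf("SimCondition: %s, mode %s, seed %d%s\n",
                conditionTag(object), object@mode, object@seed,
                if (length(object@r))
                    sprintf(", linked (%d passengers)", length(object@r))
                else ""))
})

# One generational step on raw state: select BP pairs, breed BP x Li
# offspring, return the new state plus the generation's statistics.
.stepGeneration <- function(state, cond) {
    mi <- which(state$male)
    fi <- which(!state$male)
    if (!length(mi) || !length(fi)) .infeasible(cond@BP, 0L)
    scoreLoci <- if (length(cond@r)) 1L else seq_len(ncol(state$G))
    sel <- .selectCore(state$G, mi, fi, state$litter, cond@BP, cond@mode,
                       scoreLoci)
    off <- .breedSelected(state, mi[sel$selM], fi[sel$selF], cond@Li, cond@r)
    list(state = off,
         stats = c(hObs = .hObsMatrix(off$G), hExp = .hExpMatrix(off$G),
                   meanPairPOH = mean(sel$poh)))
}

#' Run one generational step
#'
#' Selects BP breeding pairs from the population under the condition's mode,
#' breeds BP x Li offspring as the entire next (non-overlapping) generation,
#' and returns the new population together with its statistics: the new
#' generation's observed and expected heterozygosity, and the mean POH of
#' the breeders that produced it (the expected hObs of the new generation).
#' Uses the current random stream.
#'
#' @param pop a [Population-class].
#' @param cond a [SimCondition-class]; linked mode (non-empty \code{r})
#'   requires a phased population with \code{1 + length(r)} loci.
#' @return list with elements \code{population} and \code{stats} (named
#'   numeric: hObs, hExp, meanPairPOH).
#' @export
runGeneration <- function(pop, cond) {
    .checkCondShape(pop, cond)
    res <- .stepGeneration(.asState(pop), cond)
    list(population = .stateToPopulation(res$state), stats = res$stats)
}

.checkCondShape <- function(pop, cond) {
    if (length(cond@r)) {
        if (ncol(pop@genotypes) != 1L + length(cond@r))
            stop("linked mode needs 1 focal + length(r) passenger loci")
    } else if (ncol(pop@genotypes) != cond@M) {
        stop(sprintf("population has %d loci but condition requests M = %d",
                     ncol(pop@genotypes), cond@M))
    }
}

#' Run a single-replicate simulation
#'
#' Seeds the random stream from the condition, then advances the base
#' population Ge generations with [runGeneration()] semantics, recording
#' observed/expected heterozygosity per generation. Generation 0 is the base
#' population itself, before any selection, so trajectories start from the
#' base values. The run is fully determined by the base population and the
#' condition's seed.
#'
#' Fixation of all loci is not an error — selection then proceeds by the
#' random tie-break among all-zero scores and hObs stays at 0. The run is
#' truncated (with \code{attr(, "truncated") = TRUE}) only when fewer than
#' BP disjoint non-littermate pairs exist.
#'
#' In linked mode (condition with non-empty \code{r}) an unphased base is
#' phased first, inside the seeded stream, and only the focal locus (column
#' 1) enters pair scoring.
#'
#' @param base a [Population-class], generation 0.
#' @param cond a [SimCondition-class].
#' @param perLocus if \code{TRUE}, attach a per-locus observed-heterozygosity
#'   matrix ((Ge + 1) x loci) as \code{attr(, "lociHObs")} — used to follow
#'   the fate of unselected passenger loci.
#' @return data.frame with columns \code{generation} (0..Ge), \code{hObs},
#'   \code{hExp}, \code{meanPairPOH} (NA at generation 0), carrying
#'   attributes \code{truncated} and optionally \code{lociHObs}.
#' @export
runSimulation <- function(base, cond, perLocus = FALSE) {
    .checkCondShape(base, cond)
    set.seed(cond@seed)
    if (length(cond@r) && !nrow(base@hapA))
        base <- phasePopulation(base)
    state <- .asState(base)
    ge <- cond@Ge
    hobs <- hexp <- mpp <- rep(NA_real_, ge + 1L)
    hobs[1] <- .hObsMatrix(state$G)
    hexp[1] <- .hExpMatrix(state$G)
    lociH <- if (perLocus) matrix(NA_real_, ge + 1L, ncol(state$G)) else NULL
    if (perLocus) lociH[1, ] <- colMeans(state$G == 1L)
    truncated <- FALSE
    last <- ge + 1L
    for (g in seq_len(ge)) {
        res <- tryCatch(.stepGeneration(state, cond),
                        infeasibleSelection = function(e) e)
        if (inherits(res, "infeasibleSelection")) {
            truncated <- TRUE
            last <- g
            break
        }
        state <- res$state
        hobs[g + 1L] <- res$stats[["hObs"]]
        hexp[g + 1L] <- res$stats[["hExp"]]
        mpp[g + 1L] <- res$stats[["meanPairPOH"]]
        if (perLocus) lociH[g + 1L, ] <- colMeans(state$G == 1L)
    }
    keep <- seq_len(last)
    out <- data.frame(generation = keep - 1L, hObs = hobs[keep],
                      hExp = hexp[keep], meanPairPOH = mpp[keep])
    attr(out, "truncated") <- truncated
    if (perLocus) attr(out, "lociHObs") <- lociH[keep, , drop = FALSE]
    out
}

#' Run replicated simulations and aggregate
#'
#' Runs \code{nRuns} independent replicates of a condition from the same base
#' population; replicate r reseeds the stream with \code{seed + r}, so every
#' replicate (and the whole set) is reproducible from the condition alone.
#' The aggregate series is the arithmetic mean across replicates at each
#' generation, computed on the raw trajectories (smoothing, if wanted, is
#' applied afterwards for display only).
#'
#' @param base a [Population-class].
#' @param cond a [SimCondition-class].
#' @param nRuns number of replicates (>= 1).
#' @return a [TrajectoryResult-class].
#' @export
runReplicates <- function(base, cond, nRuns) {
    nRuns <- as.integer(nRuns)
    if (nRuns < 1L) stop("'nRuns' must be >= 1")
    reps <- vector("list", nRuns)
    trunc <- logical(nRuns)
    for (r in seq_len(nRuns)) {
        condR <- initialize(cond, seed = cond@seed + r)
        tr <- runSimulation(base, condR)
        trunc[r] <- attr(tr, "truncated")
        reps[[r]] <- tr
    }
    gens <- 0:max(vapply(reps, function(d) max(d$generation), numeric(1)))
    agg <- data.frame(
        generation = gens,
        hObs = .aggCol(reps, gens, "hObs"),
        hExp = .aggCol(reps, gens, "hExp"),
        meanPairPOH = .aggCol(reps, gens, "meanPairPOH"))
    new("TrajectoryResult", condition = cond, replicates = reps,
        aggregate = agg, nReplicates = nRuns, truncated = trunc)
}

# mean across the replicates that reached each generation
.aggCol <- function(reps, gens, col) {
    vapply(gens, function(g) {
        v <- unlist(lapply(reps, function(d) d[[col]][d$generation == g]))
        if (length(v)) mean(v) else NA_real_
    }, numeric(1))
}

#' Accessors for TrajectoryResult objects
#'
#' \code{trajectories()} returns the list of per-replicate data frames,
#' \code{aggregated()} the cross-replicate mean series, \code{conditionOf()}
#' the condition that was run.
#'
#' @param x a [TrajectoryResult-class].
#' @name TrajectoryResult-accessors
NULL

#' @rdname TrajectoryResult-accessors
#' @export
setMethod("trajectories", "TrajectoryResult", function(x) x@replicates)

#' @rdname TrajectoryResult-accessors
#' @export
setMethod("aggregated", "TrajectoryResult", function(x) x@aggregate)

#' @rdname TrajectoryResult-accessors
#' @export
setMethod("conditionOf", "TrajectoryResult", function(x) x@condition)

#' @export
setMethod("show", "TrajectoryResult", function(object) {
    agg <- object@aggregate
    fin <- agg[nrow(agg), ]
    cat(sprintf(
        "TrajectoryResult: %s, mode %s, %d replicate(s)%s\n",
        conditionTag(object@condition), object@condition@mode,
        object@nReplicates,
        if (any(object@truncated))
            sprintf(" (%d truncated)", sum(object@truncated)) else ""))
    cat(sprintf("  final generation %d: mean hObs = %.4f, mean hExp = %.4f\n",
                fin$generation, fin$hObs, fin$hExp))
})

#' Write trajectories as TSV
#'
#' One row per generation with columns \code{generation}, \code{hObs},
#' \code{hExp}, \code{meanPairPOH} and \code{replicate} (1..n, or
#' \code{"mean"} for the aggregate series).
#'
#' @param x a [TrajectoryResult-class] or a single trajectory data.frame.
#' @param path output file.
#' @param replicate label used when \code{x} is a bare data.frame.
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(x, path, replicate = "1") {
    if (is(x, "TrajectoryResult")) {
        parts <- lapply(seq_along(x@replicates), function(r)
            cbind(x@replicates[[r]], replicate = as.character(r)))
        parts <- c(parts, list(cbind(x@aggregate, replicate = "mean")))
        tab <- do.call(rbind, parts)
    } else {
        tab <- cbind(x, replicate = replicate)
    }
    utils::write.table(format(tab, digits = 10, trim = TRUE, scientific = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
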