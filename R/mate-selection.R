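#' Infeasible selection condition
#'
#' Raised when fewer disjoint breeding pairs can be seated than requested;
#' the condition carries the achievable count in \code{$achievable}.
#' @noRd
.infeasible <- function(requested, achievable) {
    stop(structure(
        class = c("infeasibleSelection", "error", "condition"),
        list(message = sprintf(
                 "cannot seat %d disjoint breeding pairs: only %d achievable",
                 requested, achievable),
             call = sys.call(-1), achievable = achievable)))
}

# Greedy disjoint seating over candidates ordered by `ord`.
# cm/cf: candidate male/female indices (local), returns list(sel = indices
# into candidates) or raises infeasibleSelection.
.greedySeat <- function(cm, cf, ord, bp, nm, nf) {
    usedM <- logical(nm)
    usedF <- logical(nf)
    sel <- integer(bp)
    k <- 0L
    for (i in ord) {
        m <- cm[i]; f <- cf[i]
        if (!usedM[m] && !usedF[f]) {
            usedM[m] <- TRUE
            usedF[f] <- TRUE
            k <- k + 1L
            sel[k] <- i
            if (k == bp) break
        }
    }
    if (k < bp) .infeasible(bp, k)
    sel
}

# Core selection on raw state; returns local male/female indices (into mi/fi)
# plus per-pair POH and metric scores. Shared by selectPairs() and the
# simulation hot loop. Scoring is restricted to `scoreLoci`.
.selectCore <- function(G, mi, fi, litter, bp, mode, scoreLoci = NULL) {
    if (is.null(scoreLoci)) scoreLoci <- seq_len(ncol(G))
    Gm <- G[mi, scoreLoci, drop = FALSE]
    Gf <- G[fi, scoreLoci, drop = FALSE]
    nm <- length(mi); nf <- length(fi)
    Spoh <- .scoreCross(Gm, Gf, "POH")
    ok <- !outer(litter[mi], litter[fi], "==")
    cand <- which(ok)
    if (!length(cand)) .infeasible(bp, 0L)
    cm <- ((cand - 1L) %% nm) + 1L
    cf <- ((cand - 1L) %/% nm) + 1L
    tie <- stats::runif(length(cand))
    ord <- switch(mode,
        POH = order(-Spoh[cand], tie),
        ASp = {
            Sasp <- .scoreCross(Gm, Gf, "ASp")
            order(Sasp[cand], tie)
        },
        random = order(tie))
    sel <- .greedySeat(cm, cf, ord, bp, nm, nf)
    selM <- cm[sel]; selF <- cf[sel]
    poh <- Spoh[cbind(selM, selF)]
    score <- switch(mode,
        POH = poh,
        ASp = .scoreCross(Gm, Gf, "ASp")[cbind(selM, selF)],
        random = poh)
    list(selM = selM, selF = selF, poh = poh, score = score)
}

#' Select disjoint breeding pairs
#'
#' Seats \code{bp} breeding pairs from the eligible (non-littermate) male x
#' female candidates of a population. In \code{"POH"} mode candidates are
#' ranked by descending mean POH, in \code{"ASp"} mode by ascending mean
#' allele sharing, and in \code{"random"} mode in uniformly random order;
#' the ranked list is then walked greedily, accepting a pair only while both
#' members are still unseated (monogamy: each individual breeds at most once
#' per generation). Ties are broken by a random shuffle drawn from the
#' current random stream, so equal-score pairs are seated in random order —
#' call \code{set.seed()} first for a reproducible outcome.
#'
#' @param pop a [Population-class].
#' @param bp number of pairs to seat.
#' @param mode \code{"POH"}, \code{"ASp"} or \code{"random"}.
#' @return a [SelectionOutcome-class]. If fewer than \code{bp} disjoint pairs
#'   exist, an error of class \code{"infeasibleSelection"} is raised whose
#'   condition object carries the achievable count.
#' @examples
#' pop <- Population(matrix(c(0, 2), 2, 1), sex = c("M", "F"))
#' set.seed(1)
#' selectPairs(pop, 1, "POH")
#' @export
selectPairs <- function(pop, bp, mode = c("POH", "ASp", "random")) {
    mode <- match.arg(mode)
    bp <- as.integer(bp)
    if (bp < 1L) stop("'bp' must be >= 1")
    mi <- which(pop@sex == "M")
    fi <- which(pop@sex == "F")
    if (!length(mi) || !length(fi))
        stop("population must contain at least one male and one female")
    res <- .selectCore(pop@genotypes, mi, fi, pop@litter, bp, mode)
    g <- pop@genotypes
    ids <- rownames(g)
    if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(nrow(g)))
    male <- mi[res$selM]; female <- fi[res$selF]
    asp <- vapply(seq_len(bp), function(i)
        pairScore(g[male[i], ], g[female[i], ], "ASp"), numeric(1))
    pairs <- data.frame(male = male, female = female,
                        maleId = ids[male], femaleId = ids[female],
                        poh = res$poh, asp = asp, score = res$score)
    new("SelectionOutcome", pairs = pairs,
        meanPairScore = mean(res$score), mode = mode, bp = bp)
}

#' Accessors for SelectionOutcome objects
#'
#' \code{selectedPairs()} returns the seated pairs as a data.frame;
#' \code{meanPairPOH()} the mean POH score of the seated pairs, which is the
#' expected observed heterozygosity of the offspring generation they produce.
#'
#' @param x a [SelectionOutcome-class].
#' @name SelectionOutcome-accessors
NULL

#' @rdname SelectionOutcome-accessors
#' @export
setMethod("selectedPairs", "SelectionOutcome", function(x) x@pairs)

#' @rdname SelectionOutcome-accessors
#' @export
setMethod("meanPairPOH", "SelectionOutcome", function(x) {
    if (!nrow(x@pairs)) stop("empty selection")
    mean(x@pairs$poh)
})

#' @export
setMethod("show", "SelectionOutcome", function(object) {
    cat(sprintf("SelectionOutcome: %d pairs, mode %s, mean %s score %.4f\n",
                object@bp, object@mode, object@mode, object@meanPairScore))
    print(utils::head(object@pairs, 10))
    if (nrow(object@pairs) > 10) cat("  ...\n")
})
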