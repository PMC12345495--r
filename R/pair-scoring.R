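# Per-locus score tables indexed by [g1 + 1, g2 + 1] for dosages g in {0,1,2}.
# POH: probability a Mendelian offspring of the pair is heterozygous.
# ASP: 0.25 * number of alleles the two genotypes share.
.POH_TABLE <- matrix(c(
    0.0, 0.5, 1.0,
    0.5, 0.5, 0.5,
    1.0, 0.5, 0.0), nrow = 3, byrow = TRUE)

.ASP_TABLE <- matrix(c(
    0.50, 0.25, 0.00,
    0.25, 0.50, 0.25,
    0.00, 0.25, 0.50), nrow = 3, byrow = TRUE)

.checkGeno <- function(...) {
    for (g in list(...))
        if (anyNA(g) || !all(g %in% c(0, 1, 2)))
            stop("genotypes must be 0, 1 or 2")
}

#' Single-locus pair scores
#'
#' `pohLocus()` is the probability that an offspring of the two parental
#' genotypes is heterozygous at the locus, under Mendelian segregation of a
#' biallelic marker: 1 for opposite homozygotes (AA x BB), 0 for identical
#' homozygotes, and 0.5 whenever at least one parent is heterozygous.
#' `aspLocus()` is the proportion of shared alleles, 0.25 times the number of
#' alleles (0, 1 or 2) the two genotypes have in common. `aspScaled()`
#' rescales ASp to the 0--1 range (division by 0.5) so that POH and ASp are
#' directly comparable; for every genotype pair except heterozygote x
#' heterozygote, `pohLocus() == 1 - aspScaled()`.
#'
#' All three are symmetric in their arguments and vectorised.
#'
#' @param g1,g2 parental genotypes in dosage coding \{0, 1, 2\}.
#' @return numeric score(s) in [0, 1].
#' @examples
#' pohLocus(0, 2)   # 1: AA x BB always yields AB
#' pohLocus(1, 1)   # 0.5
#' aspLocus(0, 1)   # 0.25: one shared allele
#' aspScaled(0, 0)  # 1
#' @export
pohLocus <- function(g1, g2) {
    .checkGeno(g1, g2)
    .POH_TABLE[cbind(g1 + 1, g2 + 1)]
}

#' @rdname pohLocus
#' @export
aspLocus <- function(g1, g2) {
    .checkGeno(g1, g2)
    .ASP_TABLE[cbind(g1 + 1, g2 + 1)]
}

#' @rdname pohLocus
#' @export
aspScaled <- function(g1, g2) {
    aspLocus(g1, g2) / 0.5
}

#' Multi-locus pair score
#'
#' Arithmetic mean of the per-locus POH or ASp values over the genotype
#' vectors of two prospective parents (loci are treated as unlinked, so the
#' per-locus probabilities are simply averaged).
#'
#' @param parent1,parent2 equal-length genotype vectors in \{0, 1, 2\}.
#' @param metric \code{"POH"} or \code{"ASp"}.
#' @return a single score in [0, 1].
#' @examples
#' pairScore(c(0, 1), c(2, 1), "POH")  # mean(1, 0.5) = 0.75
#' @export
pairScore <- function(parent1, parent2, metric = c("POH", "ASp")) {
    metric <- match.arg(metric)
    if (length(parent1) != length(parent2))
        stop("parental genotype vectors must have the same length")
    if (!length(parent1))
        stop("at least one locus is required")
    f <- if (metric == "POH") pohLocus else aspLocus
    mean(f(parent1, parent2))
}

# Cross score matrix (males x females) for a metric, via indicator-matrix
# products; algebraically identical to averaging the lookup table per locus
# but runs as three small BLAS multiplications.
.scoreCross <- function(Gm, Gf, metric) {
    L <- ncol(Gm)
    A1 <- (Gm == 1L) + 0
    B1 <- (Gf == 1L) + 0
    if (metric == "POH") {
        A0 <- (Gm == 0L) + 0; A2 <- (Gm == 2L) + 0
        B0 <- (Gf == 0L) + 0; B2 <- (Gf == 2L) + 0
        S <- A0 %*% t(B2) + A2 %*% t(B0)
        hm <- rowSums(A1)
        hf <- rowSums(B1)
        S <- S + 0.5 * (outer(hm, rep(1, nrow(Gf))) +
                        outer(rep(1, nrow(Gm)), hf) - A1 %*% t(B1))
    } else {
        A0 <- (Gm == 0L) + 0; A2 <- (Gm == 2L) + 0
        B0 <- (Gf == 0L) + 0; B2 <- (Gf == 2L) + 0
        shared2 <- A0 %*% t(B0) + A1 %*% t(B1) + A2 %*% t(B2)
        shared1 <- (A0 + A2) %*% t(B1) + A1 %*% t(B0 + B2)
        S <- 0.25 * (2 * shared2 + shared1)
    }
    S / L
}

#' Enumerate eligible breeding pairs
#'
#' All male x female combinations except littermates (pairs sharing a litter
#' id, i.e. produced by the same parental pair in the same generation).
#' Returns a zero-row data frame when no pair is eligible.
#'
#' @param pop a [Population-class] with at least one male and one female.
#' @return data.frame with columns \code{male} and \code{female} (row indices
#'   into the population); no scores attached.
#' @export
eligiblePairs <- function(pop) {
    mi <- which(pop@sex == "M")
    fi <- which(pop@sex == "F")
    if (!length(mi) || !length(fi))
        stop("population must contain at least one male and one female")
    ok <- !outer(pop@litter[mi], pop@litter[fi], "==")
    idx <- which(ok, arr.ind = TRUE)
    data.frame(male = mi[idx[, 1]], female = fi[idx[, 2]])
}

#' Score all eligible pairs as a mating plan
#'
#' The applied entry point for a real cohort: every eligible male x female
#' pair with its multi-locus POH and ASp scores, ranked by the requested
#' metric (POH descending, ASp ascending).
#'
#' @param pop a [Population-class].
#' @param rankBy metric to sort by.
#' @return data.frame with columns \code{maleId}, \code{femaleId},
#'   \code{POH}, \code{ASp}.
#' @seealso [writeMatingPlan()]
#' @export
matingPlan <- function(pop, rankBy = c("POH", "ASp")) {
    rankBy <- match.arg(rankBy)
    cand <- eligiblePairs(pop)
    g <- pop@genotypes
    ids <- rownames(g)
    if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(nrow(g)))
    if (!nrow(cand)) {
        warning("no eligible pairs (all cross-sex pairs are littermates)")
        return(data.frame(maleId = character(0), femaleId = character(0),
                          POH = numeric(0), ASp = numeric(0)))
    }
    mi <- sort(unique(cand$male)); fi <- sort(unique(cand$female))
    Sp <- .scoreCross(g[mi, , drop = FALSE], g[fi, , drop = FALSE], "POH")
    Sa <- .scoreCross(g[mi, , drop = FALSE], g[fi, , drop = FALSE], "ASp")
    im <- match(cand$male, mi); jf <- match(cand$female, fi)
    out <- data.frame(maleId = ids[cand$male], femaleId = ids[cand$female],
                      POH = Sp[cbind(im, jf)], ASp = Sa[cbind(im, jf)])
    ord <- if (rankBy == "POH") order(-out$POH, out$ASp)
           else order(out$ASp, -out$POH)
    out[ord, , drop = FALSE]
}

#' @param plan a data.frame from [matingPlan()].
#' @param path output TSV file.
#' @rdname matingPlan
#' @export
writeMatingPlan <- function(plan, path) {
    utils::write.table(plan, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
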