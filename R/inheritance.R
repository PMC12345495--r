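# One gamete allele matrix for a matrix of parent genotype rows: homozygotes
# transmit their allele, heterozygotes transmit either with probability 1/2.
.mendelGametes <- function(P) {
    (P == 2L) + ((P == 1L) & (stats::runif(length(P)) < 0.5))
}

# Linked gametes for parents given as haplotype matrices. The focal locus
# (column 1) is drawn from either haplotype with probability 1/2; each
# passenger locus i co-segregates with the focal one with probability
# 1 - r[i] and recombines with probability r[i], independently.
.linkedGametes <- function(HA, HB, r) {
    n <- nrow(HA); L <- ncol(HA)
    src <- matrix(FALSE, n, L)
    src[, 1] <- stats::runif(n) < 0.5
    if (L > 1L) {
        flip <- matrix(stats::runif(n * (L - 1L)), n) < rep(r, each = n)
        src[, -1] <- xor(src[, 1], flip)
    }
    HB + src * (HA - HB)
}

#' Draw a gamete from an unlinked multi-locus genotype
#'
#' Mendelian segregation with independent loci: a homozygote transmits its
#' allele with certainty, a heterozygote transmits either allele with
#' probability 1/2. Uses the current random stream.
#'
#' @param parent genotype vector in \{0, 1, 2\}.
#' @return integer vector of transmitted allele-B counts (0/1), one per locus.
#' @export
gameteUnlinked <- function(parent) {
    .checkGeno(parent)
    as.integer(.mendelGametes(matrix(as.integer(parent), 1)))
}

#' Draw a gamete from a phased haplotype pair with linkage
#'
#' Locus 1 is the focal locus; its allele comes from either parental
#' haplotype with probability 1/2. Each remaining (passenger) locus inherits
#' from the same haplotype as the focal locus with probability \code{1 - r}
#' and from the other with probability \code{r}, independently across
#' passengers (pairwise recombination fractions, no interference).
#' With all \code{r = 0} the gamete is one complete parental haplotype;
#' with \code{r = 0.5} a passenger segregates independently of the focal
#' locus.
#'
#' @param hapA,hapB parental haplotypes, 0/1 allele vectors of equal length.
#' @param r recombination fractions in [0, 0.5], length \code{length(hapA) - 1}.
#' @return integer allele vector of the gamete.
#' @export
gameteLinked <- function(hapA, hapB, r) {
    if (length(hapA) != length(hapB))
        stop("haplotypes must have equal length")
    if (length(r) != length(hapA) - 1L)
        stop("'r' must have one entry per passenger locus")
    if (any(r < 0) || any(r > 0.5))
        stop("recombination fractions must lie in [0, 0.5]")
    as.integer(.linkedGametes(matrix(as.integer(hapA), 1),
                              matrix(as.integer(hapB), 1), r))
}

# sexes of one litter: half male, half female; for odd litter sizes the
# extra individual alternates sex with the litter's index.
.litterSexFlags <- function(li, litterIndex) {
    nM <- li %/% 2L + if (li %% 2L == 1L && litterIndex %% 2L == 1L) 1L else 0L
    c(rep(TRUE, nM), rep(FALSE, li - nM))
}

# Breed the selected pairs into the full next generation (internal, state
# level). sidx/didx: population row indices of sire/dam per pair.
.breedSelected <- function(state, sidx, didx, li, r = numeric(0)) {
    bp <- length(sidx)
    srow <- sidx[rep(seq_len(bp), each = li)]
    drow <- didx[rep(seq_len(bp), each = li)]
    linked <- length(r) > 0L
    if (linked) {
        hapA <- .linkedGametes(state$hapA[srow, , drop = FALSE],
                               state$hapB[srow, , drop = FALSE], r)
        hapB <- .linkedGametes(state$hapA[drow, , drop = FALSE],
                               state$hapB[drow, , drop = FALSE], r)
        G <- hapA + hapB
    } else {
        hapA <- hapB <- matrix(integer(0), 0, 0)
        G <- .mendelGametes(state$G[srow, , drop = FALSE]) +
             .mendelGametes(state$G[drow, , drop = FALSE])
    }
    storage.mode(G) <- "integer"
    if (linked) {
        storage.mode(hapA) <- "integer"
        storage.mode(hapB) <- "integer"
    }
    gen <- state$generation + 1L
    male <- unlist(lapply(seq_len(bp), function(l) .litterSexFlags(li, l)))
    litter <- sprintf("g%d.l%d", gen, rep(seq_len(bp), each = li))
    list(G = G, male = male, litter = litter, hapA = hapA, hapB = hapB,
         generation = gen)
}

#' Produce one litter from a breeding pair
#'
#' Each offspring genotype is the sum of one Mendelian gamete from the sire
#' and one from the dam (independent loci; or linked segregation when the
#' population is phased and \code{r} is supplied). All offspring share a
#' fresh litter id, and sexes follow the fixed half/half composition (2 M +
#' 2 F for a litter of four; for odd sizes the extra sex alternates between
#' litters, here resolved as male).
#'
#' @param pop a [Population-class].
#' @param male,female row indices of the sire and dam (opposite sexes).
#' @param li litter size (>= 1).
#' @param r optional recombination fractions enabling linked segregation;
#'   requires a phased population (see [phasePopulation()]).
#' @return a [Population-class] holding the litter, generation index one
#'   above the parents'.
#' @export
makeLitter <- function(pop, male, female, li, r = numeric(0)) {
    li <- as.integer(li)
    if (li < 1L) stop("'li' must be >= 1")
    if (pop@sex[male] == pop@sex[female])
        stop("breeding pair must consist of one male and one female")
    if (length(r) && !nrow(pop@hapA))
        stop("linked segregation requires a phased population")
    state <- .asState(pop)
    off <- .breedSelected(state, male, female, li, r)
    .stateToPopulation(off)
}
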