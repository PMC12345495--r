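#' Synthesize a founder cohort
#'
#' Generates a base population with the statistical shape of the real founder
#' cohort the method was developed on: a fixed sex ratio, unlinked biallelic
#' SNPs whose minor allele frequency is drawn uniformly on
#' \code{(mafLow, mafHigh]}, and Hardy-Weinberg genotypes (dosage ~
#' Binomial(2, q) per individual and locus). Defaults reproduce a cohort of
#' 29 males and 41 females typed at 51 high-MAF SNPs (MAF > 0.4).
#'
#' Frequencies are drawn above \code{mafLow}, but the realised sample MAF of
#' a locus may fall below it; synthetic loci are deliberately not re-filtered
#' so the locus count stays fixed (the MAF filter applies to real-data
#' ingestion).
#'
#' @param nMales,nFemales founder sex counts.
#' @param nLoci number of unlinked SNPs.
#' @param mafLow,mafHigh frequency bounds, \code{0 <= mafLow < mafHigh <= 0.5}.
#' @param seed integer seed; identical seeds give identical populations.
#' @return a [Population-class], generation 0, each founder in its own
#'   litter (founders are never littermates).
#' @examples
#' base <- synthesizeBase(seed = 1)
#' hExp(base)
#' @export
synthesizeBase <- function(nMales = 29, nFemales = 41, nLoci = 51,
                           mafLow = 0.4, mafHigh = 0.5, seed = 1L) {
    n <- nMales + nFemales
    if (n < 1L) stop("at least one individual is required")
    if (mafLow < 0 || mafLow >= mafHigh || mafHigh > 0.5)
        stop("need 0 <= mafLow < mafHigh <= 0.5")
    set.seed(seed)
    # uniform on (mafLow, mafHigh]: complement of runif's [0, 1) on the width
    q <- mafHigh - stats::runif(nLoci) * (mafHigh - mafLow)
    G <- matrix(stats::rbinom(n * nLoci, 2L, rep(q, each = n)), n, nLoci)
    rownames(G) <- sprintf("F0_%03d", seq_len(n))
    colnames(G) <- sprintf("SNP%03d", seq_len(nLoci))
    Population(G, c(rep("M", nMales), rep("F", nFemales)))
}
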