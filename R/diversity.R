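#' Observed and expected heterozygosity of a generation
#'
#' \code{hObs()} is the observed heterozygosity: the per-locus fraction of
#' heterozygous animals, averaged over loci and then over individuals. Since
#' the per-individual average of a per-locus population fraction is an
#' identity, this equals the overall fraction of heterozygous genotype calls
#' in the matrix.
#'
#' \code{hExp()} is the expected heterozygosity (gene diversity): 2 p q from
#' the generation's realised allele frequencies at each locus, averaged over
#' loci (the subsequent per-individual averaging step is likewise an
#' identity). For biallelic loci \code{hExp() <= 0.5} always, whereas
#' \code{hObs()} can reach 1.
#'
#' @param x a [Population-class] (or a dosage matrix).
#' @return a single value in [0, 1].
#' @examples
#' pop <- Population(matrix(1, 3, 2), sex = c("M", "F", "F"))
#' hObs(pop)  # 1
#' hExp(pop)  # 0.5
#' @name hObs
NULL

.hObsMatrix <- function(g) {
    if (!length(g)) stop("empty population")
    mean(g == 1L)
}

.hExpMatrix <- function(g) {
    if (!length(g)) stop("empty population")
    q <- colMeans(g) / 2
    mean(2 * q * (1 - q))
}

#' @rdname hObs
#' @export
setMethod("hObs", "Population", function(x) .hObsMatrix(x@genotypes))

#' @rdname hObs
#' @export
setMethod("hObs", "matrix", function(x) .hObsMatrix(x))

#' @rdname hObs
#' @export
setMethod("hExp", "Population", function(x) .hExpMatrix(x@genotypes))

#' @rdname hObs
#' @export
setMethod("hExp", "matrix", function(x) .hExpMatrix(x))

#' Exponentially weighted moving average
#'
#' Span-parameterised EWMA used to smooth heterozygosity trajectories for
#' display. Element n of the result is the weighted mean of the first n
#' observations with weights \eqn{(1-\alpha)^j} on the value j steps back,
#' where \eqn{\alpha = 2 / (span + 1)}:
#' \deqn{s_n = \frac{\sum_{j=0}^{n} (1-\alpha)^j x_{n-j}}
#'            {\sum_{j=0}^{n} (1-\alpha)^j}.}
#' Smoothing is for display only; replicate aggregation always averages the
#' raw series.
#'
#' @param series numeric vector; an empty vector returns an empty vector.
#' @param span number of values spanned in a period (>= 1); span 1 gives
#'   \eqn{\alpha = 1}, i.e. no memory.
#' @return numeric vector of the same length.
#' @examples
#' ewmaSmooth(c(1, 0), span = 3)  # c(1, 1/3)
#' @export
ewmaSmooth <- function(series, span = 10) {
    if (length(span) != 1L || span < 1) stop("'span' must be >= 1")
    n <- length(series)
    if (!n) return(numeric(0))
    alpha <- 2 / (span + 1)
    beta <- 1 - alpha
    out <- numeric(n)
    s <- 0
    w <- 0
    for (i in seq_len(n)) {
        s <- series[i] + beta * s
        w <- 1 + beta * w
        out[i] <- s / w
    }
    out
}
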