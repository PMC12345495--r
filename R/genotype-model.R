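#' Allele frequencies at a locus
#'
#' For a biallelic locus in allele-B dosage coding, returns the frequencies
#' of allele A (\code{p}) and allele B (\code{q}): \code{p = 1 - sum(dosage) /
#' (2 * n)} and \code{q = 1 - p}.
#'
#' @param x a [Population-class] or a dosage matrix.
#' @param locus column index of the locus.
#' @return named numeric vector \code{c(p = , q = )} with \code{p + q == 1}.
#' @examples
#' alleleFreq(matrix(c(0, 0, 2, 2), 4, 1), 1)  # c(p = 0.5, q = 0.5)
#' @export
alleleFreq <- function(x, locus) {
    g <- if (is(x, "Population")) x@genotypes else as.matrix(x)
    if (nrow(g) < 1L || ncol(g) < 1L)
        stop("empty genotype matrix")
    if (locus < 1L || locus > ncol(g))
        stop("locus index out of range")
    q <- sum(g[, locus]) / (2 * nrow(g))
    c(p = 1 - q, q = q)
}

#' Filter loci by minor allele frequency
#'
#' Keeps loci whose minor allele frequency min(p, q) strictly exceeds the
#' threshold (a locus with MAF exactly at the threshold is dropped), mirroring
#' the "MAF greater than 0.4" marker-panel rule used to assemble the SNP set.
#'
#' @param x a [Population-class] or a dosage matrix.
#' @param threshold MAF threshold in [0, 0.5).
#' @return integer vector of retained locus (column) indices. At threshold 0
#'   this is exactly the polymorphic loci.
#' @export
mafFilter <- function(x, threshold) {
    g <- if (is(x, "Population")) x@genotypes else as.matrix(x)
    if (length(threshold) != 1L || threshold < 0 || threshold >= 0.5)
        stop("'threshold' must lie in [0, 0.5)")
    q <- colSums(g) / (2 * nrow(g))
    maf <- pmin(q, 1 - q)
    which(maf > threshold)
}

#' Read a genotype table
#'
#' Reads a delimited text table (tab or whitespace separated, header row)
#' in a dialect of the PLINK .raw additive coding: columns \code{id},
#' \code{sex} (M/F), an optional \code{litter} column, then one column per
#' locus with dosage values 0/1/2. Missing genotype calls are rejected
#' (a call rate of 1 is required), as is any value outside \{0, 1, 2\}.
#'
#' @param path file to read.
#' @param sep field separator passed to [utils::read.table()]; the default
#'   \code{""} accepts any whitespace, including tabs.
#' @return a [Population-class] with generation index 0.
#' @seealso [writePopulation()] for the inverse; a written table reloads to an
#'   identical population.
#' @export
loadPopulation <- function(path, sep = "") {
    if (!file.exists(path))
        stop("genotype table not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE)
    cn <- tolower(names(tab))
    if (length(tab) < 3L || cn[1] != "id" || cn[2] != "sex")
        stop("expected columns: id, sex, [litter], then one column per locus")
    hasLitter <- length(tab) >= 3L && cn[3] == "litter"
    first <- if (hasLitter) 4L else 3L
    if (length(tab) < first)
        stop("no genotype columns found")
    g <- as.matrix(tab[, first:length(tab), drop = FALSE])
    if (anyNA(g))
        stop("missing genotype calls are not allowed (call rate must be 1)")
    if (!is.numeric(g) || !all(g %in% c(0, 1, 2)))
        stop("genotype values must be 0, 1 or 2")
    rownames(g) <- as.character(tab[[1]])
    Population(g, tab[[2]],
               litter = if (hasLitter) as.character(tab[[3]]) else NULL)
}

#' Write a population as a genotype table
#'
#' Tab-separated, one row per individual: id, sex, litter, then the dosage
#' at each locus. Readable back with [loadPopulation()].
#'
#' @param pop a [Population-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePopulation <- function(pop, path) {
    g <- pop@genotypes
    ids <- rownames(g)
    if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(nrow(g)))
    loci <- colnames(g)
    if (is.null(loci)) loci <- sprintf("L%03d", seq_len(ncol(g)))
    out <- data.frame(id = ids, sex = pop@sex, litter = pop@litter,
                      g, check.names = FALSE)
    names(out) <- c("id", "sex", "litter", loci)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
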