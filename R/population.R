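#' Construct a Population
#'
#' @param genotypes numeric/integer matrix (individuals x loci) with entries
#'   in \{0, 1, 2\} counting copies of allele B. Row names, if present, are
#'   used as individual ids.
#' @param sex character vector of \code{"M"}/\code{"F"} labels (case
#'   insensitive; \code{"male"}/\code{"female"} accepted).
#' @param litter optional character vector of litter (parental-pair) ids;
#'   defaults to a unique id per individual, so founders are never treated as
#'   littermates.
#' @param generation generation index, 0 for a base population.
#' @param hapA,hapB optional phased haplotype matrices (0/1 alleles) summing
#'   to \code{genotypes}; only used in linked-locus mode.
#'
#' @return A [Population-class] object.
#' @examples
#' pop <- Population(matrix(c(0, 2, 1, 1), 2, 2), sex = c("M", "F"))
#' hObs(pop)
#' @export
Population <- function(genotypes, sex, litter = NULL, generation = 0L,
                       hapA = NULL, hapB = NULL) {
    genotypes <- as.matrix(genotypes)
    storage.mode(genotypes) <- "integer"
    sex <- .normalizeSex(sex)
    if (is.null(litter))
        litter <- sprintf("ind%04d", seq_len(nrow(genotypes)))
    empty <- matrix(integer(0), 0, 0)
    if (is.null(hapA)) hapA <- empty else storage.mode(hapA) <- "integer"
    if (is.null(hapB)) hapB <- empty else storage.mode(hapB) <- "integer"
    new("Population", genotypes = genotypes, sex = sex,
        litter = as.character(litter), generation = as.integer(generation),
        hapA = hapA, hapB = hapB)
}

.normalizeSex <- function(sex) {
    s <- toupper(as.character(sex))
    s[s %in% c("MALE", "M", "1")] <- "M"
    s[s %in% c("FEMALE", "F", "2")] <- "F"
    bad <- !s %in% c("M", "F")
    if (any(bad))
        stop("unknown sex label(s): ", paste(unique(sex[bad]), collapse = ", "))
    s
}

#' Accessors for Population objects
#'
#' @param x a [Population-class].
#' @return \code{genotypes()} the dosage matrix; \code{sexes()} and
#'   \code{litters()} the per-individual labels; \code{generationIndex()} the
#'   generation number; \code{nIndividuals()} / \code{nLoci()} the matrix
#'   dimensions.
#' @name Population-accessors
NULL

#' @rdname Population-accessors
#' @export
setMethod("genotypes", "Population", function(x) x@genotypes)

#' @rdname Population-accessors
#' @export
setMethod("sexes", "Population", function(x) x@sex)

#' @rdname Population-accessors
#' @export
setMethod("litters", "Population", function(x) x@litter)

#' @rdname Population-accessors
#' @export
setMethod("generationIndex", "Population", function(x) x@generation)

#' @rdname Population-accessors
#' @export
setMethod("nIndividuals", "Population", function(x) nrow(x@genotypes))

#' @rdname Population-accessors
#' @export
setMethod("nLoci", "Population", function(x) ncol(x@genotypes))

#' @export
setMethod("show", "Population", function(object) {
    cat(sprintf(
        "Population: %d individuals (%d M / %d F) x %d loci, generation %d%s\n",
        nrow(object@genotypes), sum(object@sex == "M"),
        sum(object@sex == "F"), ncol(object@genotypes), object@generation,
        if (nrow(object@hapA)) ", phased" else ""))
    cat(sprintf("  hObs = %.4f, hExp = %.4f\n", hObs(object), hExp(object)))
})

#' Phase a population for linked-locus simulation
#'
#' Assigns each individual two haplotypes consistent with its genotypes:
#' homozygous loci are forced, heterozygous loci place the B allele on either
#' haplotype with probability 1/2. Phasing consumes the current random stream;
#' call \code{set.seed()} beforehand for reproducibility.
#'
#' @param pop a [Population-class] without phase information.
#' @return The same population with \code{hapA}/\code{hapB} filled in.
#' @export
phasePopulation <- function(pop) {
    g <- pop@genotypes
    het <- g == 1L
    hapA <- (g == 2L) + (het & matrix(stats::runif(length(g)) < 0.5, nrow(g)))
    storage.mode(hapA) <- "integer"
    hapB <- g - hapA
    initialize(pop, hapA = hapA, hapB = hapB)
}

# internal lightweight state used by the simulation hot loop
.asState <- function(pop) {
    list(G = pop@genotypes, male = pop@sex == "M", litter = pop@litter,
         hapA = pop@hapA, hapB = pop@hapB, generation = pop@generation)
}

.stateToPopulation <- function(state) {
    Population(state$G, ifelse(state$male, "M", "F"), state$litter,
               generation = state$generation,
               hapA = if (nrow(state$hapA)) state$hapA else NULL,
               hapB = if (nrow(state$hapB)) state$hapB else NULL)
}
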