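#' @import methods
NULL

.VALID_MODES <- c("POH", "ASp", "random")

#' Population of genotyped individuals
#'
#' Central container for a (possibly simulated) generation: a biallelic
#' genotype matrix in allele-B dosage coding, per-individual sex labels and
#' litter identifiers, and the generation index. In linked mode the two
#' parental haplotypes are carried alongside the genotypes.
#'
#' @slot genotypes integer matrix, individuals x loci, entries in \{0, 1, 2\}
#'   (copies of allele B: 0 = AA, 1 = AB, 2 = BB).
#' @slot sex character vector, one of \code{"M"} or \code{"F"} per individual.
#' @slot litter character vector identifying the parental pair that produced
#'   each individual; founders carry unique ids so no two founders are treated
#'   as littermates.
#' @slot generation single non-negative integer, 0 for the base population.
#' @slot hapA,hapB integer matrices of per-locus alleles (0/1) for the two
#'   parental haplotypes, or 0 x 0 matrices when phase is not tracked.
#'
#' @seealso [Population()] for the user-facing constructor,
#'   [synthesizeBase()] and [loadPopulation()] for ways to obtain one.
#' @export
setClass("Population",
    slots = c(
        genotypes = "matrix",
        sex = "character",
        litter = "character",
        generation = "integer",
        hapA = "matrix",
        hapB = "matrix"
    ),
    prototype = prototype(
        generation = 0L,
        hapA = matrix(integer(0), 0, 0),
        hapB = matrix(integer(0), 0, 0)
    )
)

setValidity("Population", function(object) {
    g <- object@genotypes
    if (!is.numeric(g) || nrow(g) < 1L || ncol(g) < 1L)
        return("'genotypes' must be a numeric matrix with >= 1 individual and >= 1 locus")
    if (anyNA(g))
        return("missing genotype calls are not allowed (complete calls required)")
    if (!all(g %in% c(0L, 1L, 2L)))
        return("genotype entries must be 0, 1 or 2 (allele-B dosage)")
    n <- nrow(g)
    if (length(object@sex) != n)
        return("'sex' must have one entry per individual")
    if (!all(object@sex %in% c("M", "F")))
        return("sex labels must be 'M' or 'F'")
    if (length(object@litter) != n)
        return("'litter' must have one entry per individual")
    if (length(object@generation) != 1L || is.na(object@generation) ||
        object@generation < 0L)
        return("'generation' must be a single non-negative integer")
    phased <- nrow(object@hapA) > 0L || nrow(object@hapB) > 0L
    if (phased) {
        if (!identical(dim(object@hapA), dim(g)) ||
            !identical(dim(object@hapB), dim(g)))
            return("haplotype matrices must match the genotype dimensions")
        if (!all(object@hapA %in% 0:1) || !all(object@hapB %in% 0:1))
            return("haplotype entries must be 0 or 1")
        if (!all(object@hapA + object@hapB == g))
            return("hapA + hapB must reproduce the genotype matrix")
    }
    TRUE
})

#' Simulation condition
#'
#' Bundle of the parameters that define one experimental arrangement:
#' the marker count M, the number of breeding pairs BP seated per generation,
#' the litter size Li, the number of simulated generations Ge, the selection
#' mode, and the base seed of the random stream. Conditions are conventionally
#' written as tags such as \code{"M51-BP10-Li4-Ge50"}; see [parseCondition()].
#'
#' @slot M,BP,Li,Ge positive integers (markers, breeding pairs, litter size,
#'   generations).
#' @slot mode one of \code{"POH"} (maximise probability of offspring
#'   heterozygosity), \code{"ASp"} (minimise allele sharing) or
#'   \code{"random"}.
#' @slot seed single integer seeding the simulation random stream.
#' @slot r numeric vector of recombination fractions for passenger loci in
#'   linked mode (each in [0, 0.5]); empty for the default unlinked mode.
#'
#' @export
setClass("SimCondition",
    slots = c(
        M = "integer", BP = "integer", Li = "integer", Ge = "integer",
        mode = "character", seed = "integer", r = "numeric"
    ),
    prototype = prototype(mode = "POH", seed = 1L, r = numeric(0))
)

setValidity("SimCondition", function(object) {
    for (s in c("M", "BP", "Li", "Ge")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v) || v < 1L)
            return(sprintf("'%s' must be a single integer >= 1", s))
    }
    if (length(object@mode) != 1L || !object@mode %in% .VALID_MODES)
        return(sprintf("'mode' must be one of %s",
                       paste(.VALID_MODES, collapse = ", ")))
    if (length(object@seed) != 1L || is.na(object@seed))
        return("'seed' must be a single integer")
    if (length(object@r)) {
        if (any(is.na(object@r)) || any(object@r < 0) || any(object@r > 0.5))
            return("recombination fractions must lie in [0, 0.5]")
        if (object@M != 1L)
            return("linked mode scores a single focal locus (M must be 1)")
    }
    TRUE
})

#' Outcome of one mate-selection step
#'
#' The BP disjoint breeding pairs chosen from a population, with their
#' per-pair POH and ASp scores, plus the mean score under the selection
#' metric. No individual appears in more than one pair (monogamy).
#'
#' @slot pairs data.frame with columns \code{male}, \code{female} (row indices
#'   into the population), \code{maleId}, \code{femaleId}, \code{poh},
#'   \code{asp} and \code{score} (the metric actually ranked on).
#' @slot meanPairScore mean of \code{score} over the seated pairs.
#' @slot mode selection mode used.
#' @slot bp number of pairs requested (and seated).
#'
#' @export
setClass("SelectionOutcome",
    slots = c(
        pairs = "data.frame",
        meanPairScore = "numeric",
        mode = "character",
        bp = "integer"
    )
)

setValidity("SelectionOutcome", function(object) {
    p <- object@pairs
    need <- c("male", "female", "poh", "asp", "score")
    if (!all(need %in% names(p)))
        return("pairs must carry male, female, poh, asp and score columns")
    if (nrow(p) != object@bp)
        return("number of seated pairs must equal the requested BP")
    if (anyDuplicated(p$male) || anyDuplicated(p$female))
        return("an individual may be seated in at most one breeding pair")
    if (any(p$poh < 0 | p$poh > 1) || any(p$asp < 0 | p$asp > 1))
        return("pair scores must lie in [0, 1]")
    TRUE
})

#' Replicated simulation trajectories
#'
#' Per-generation observed/expected heterozygosity and mean pair POH for each
#' replicate of a simulation condition, plus the cross-replicate arithmetic
#' mean per generation. Generation 0 (the base population) is always included.
#'
#' @slot condition the [SimCondition-class] that was run.
#' @slot replicates list of per-replicate data.frames with columns
#'   \code{generation}, \code{hObs}, \code{hExp}, \code{meanPairPOH}.
#' @slot aggregate data.frame of the per-generation means across replicates.
#' @slot nReplicates number of replicates run.
#' @slot truncated logical per replicate: \code{TRUE} if the run stopped early
#'   because not enough disjoint pairs could be seated.
#'
#' @export
setClass("TrajectoryResult",
    slots = c(
        condition = "SimCondition",
        replicates = "list",
        aggregate = "data.frame",
        nReplicates = "integer",
        truncated = "logical"
    )
)

setValidity("TrajectoryResult", function(object) {
    if (length(object@replicates) != object@nReplicates)
        return("'replicates' length must equal nReplicates")
    if (length(object@truncated) != object@nReplicates)
        return("'truncated' length must equal nReplicates")
    TRUE
})
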