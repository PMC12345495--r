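#' @rdname Population-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname Population-accessors
#' @export
setGeneric("sexes", function(x) standardGeneric("sexes"))

#' @rdname Population-accessors
#' @export
setGeneric("litters", function(x) standardGeneric("litters"))

#' @rdname Population-accessors
#' @export
setGeneric("generationIndex", function(x) standardGeneric("generationIndex"))

#' @rdname Population-accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname Population-accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname hObs
#' @export
setGeneric("hObs", function(x) standardGeneric("hObs"))

#' @rdname hObs
#' @export
setGeneric("hExp", function(x) standardGeneric("hExp"))

#' @rdname SelectionOutcome-accessors
#' @export
setGeneric("selectedPairs", function(x) standardGeneric("selectedPairs"))

#' @rdname SelectionOutcome-accessors
#' @export
setGeneric("meanPairPOH", function(x) standardGeneric("meanPairPOH"))

#' @rdname TrajectoryResult-accessors
#' @export
setGeneric("trajectories", function(x) standardGeneric("trajectories"))

#' @rdname TrajectoryResult-accessors
#' @export
setGeneric("aggregated", function(x) standardGeneric("aggregated"))

#' @rdname TrajectoryResult-accessors
#' @export
setGeneric("conditionOf", function(x) standardGeneric("conditionOf"))
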