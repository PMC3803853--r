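#' Accessors for SyntheticEyeData
#'
#' @param x a \linkS4class{SyntheticEyeData}
#' @return the corresponding slot: sequence sets, tables or the config.
#' @name accessors
#' @examples
#' d <- generateDataset(SimulationConfig(nFamilies = 12, nDuplications = 1,
#'   nDualOriginDuplications = 0, nSelectionEvents = 1, nQcDecoys = 0,
#'   nConservedDecoys = 0, seed = 3))
#' length(humanProteins(d))
#' head(truthContigs(d))
NULL

#' @rdname accessors
#' @export
setGeneric("humanProteins", function(x) standardGeneric("humanProteins"))
#' @rdname accessors
#' @export
setGeneric("flyProteins", function(x) standardGeneric("flyProteins"))
#' @rdname accessors
#' @export
setGeneric("nautilusContigs", function(x) standardGeneric("nautilusContigs"))
#' @rdname accessors
#' @export
setGeneric("squidContigs", function(x) standardGeneric("squidContigs"))
#' @rdname accessors
#' @export
setGeneric("coverageTable", function(x) standardGeneric("coverageTable"))
#' @rdname accessors
#' @export
setGeneric("goMap", function(x) standardGeneric("goMap"))
#' @rdname accessors
#' @export
setGeneric("homologueMap", function(x) standardGeneric("homologueMap"))
#' @rdname accessors
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))
#' @rdname accessors
#' @export
setGeneric("truthContigs", function(x) standardGeneric("truthContigs"))

#' @rdname accessors
setMethod("humanProteins", "SyntheticEyeData", function(x) x@humanProteins)
#' @rdname accessors
setMethod("flyProteins", "SyntheticEyeData", function(x) x@flyProteins)
#' @rdname accessors
setMethod("nautilusContigs", "SyntheticEyeData", function(x) x@nautilusContigs)
#' @rdname accessors
setMethod("squidContigs", "SyntheticEyeData", function(x) x@squidContigs)
#' @rdname accessors
setMethod("coverageTable", "SyntheticEyeData", function(x) x@coverage)
#' @rdname accessors
setMethod("goMap", "SyntheticEyeData", function(x) x@goMap)
#' @rdname accessors
setMethod("homologueMap", "SyntheticEyeData", function(x) x@homologueMap)
#' @rdname accessors
setMethod("truthEvents", "SyntheticEyeData", function(x) x@truthEvents)
#' @rdname accessors
setMethod("truthContigs", "SyntheticEyeData", function(x) x@truthContigs)
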