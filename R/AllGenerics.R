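#' @include AllClasses.R
NULL

#' @rdname exprValues
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname betaValues
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname sampleSheet
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' @rdname probeAnnotation
#' @export
setGeneric("probeAnnotation", function(x) standardGeneric("probeAnnotation"))

#' @rdname truthTable
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname geneSets
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname universeSize
#' @export
setGeneric("universeSize", function(x) standardGeneric("universeSize"))

#' @rdname riskGenes
#' @export
setGeneric("riskGenes", function(x) standardGeneric("riskGenes"))

#' @rdname unannotatedProbes
#' @export
setGeneric("unannotatedProbes", function(x) standardGeneric("unannotatedProbes"))
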