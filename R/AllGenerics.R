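#' @import methods
NULL

#' @export
setGeneric("precursorIds", function(x) standardGeneric("precursorIds"))

#' @export
setGeneric("hasSignalPeptide", function(x) standardGeneric("hasSignalPeptide"))

#' @export
setGeneric("signalCleavagePos", function(x) standardGeneric("signalCleavagePos"))

#' @export
setGeneric("attachSignalAnnotations",
    function(x, annotations) standardGeneric("attachSignalAnnotations"))

#' @export
setGeneric("kepCalls", function(x) standardGeneric("kepCalls"))

#' @export
setGeneric("acceptedIds", function(x) standardGeneric("acceptedIds"))

#' @export
setGeneric("fragments", function(x, id = NULL) standardGeneric("fragments"))

#' @export
setGeneric("similarityEdges", function(x, id = NULL)
    standardGeneric("similarityEdges"))

#' @export
setGeneric("miningConfig", function(x) standardGeneric("miningConfig"))
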