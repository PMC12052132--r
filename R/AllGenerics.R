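#' @rdname timeMeasures
#' @export
setGeneric("modifiedSteps", function(x) standardGeneric("modifiedSteps"))

#' @rdname timeMeasures
#' @export
setGeneric("classicSteps", function(x) standardGeneric("classicSteps"))

#' @rdname timeMeasures
#' @export
setGeneric("realTime", function(x) standardGeneric("realTime"))

#' @rdname MoranGraph-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname MoranGraph-accessors
#' @export
setGeneric("outNeighbors", function(x, node) standardGeneric("outNeighbors"))

#' @rdname MoranGraph-accessors
#' @export
setGeneric("outDegree", function(x, node) standardGeneric("outDegree"))

#' @rdname MoranGraph-accessors
#' @export
setGeneric("graphFamily", function(x) standardGeneric("graphFamily"))

#' @rdname MoranGraph-accessors
#' @export
setGeneric("defaultStart", function(x) standardGeneric("defaultStart"))

#' @rdname MoranGraph-accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))
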