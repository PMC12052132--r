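#' Accessors for MoranGraph objects
#'
#' @param x A [MoranGraph-class].
#' @param node Optional node index; when missing, `outNeighbors` returns the
#'   full adjacency list and `outDegree` the vector of all out-degrees.
#'
#' @return `numNodes` and `numEdges` return integer scalars; `outDegree` an
#'   integer vector (or scalar); `outNeighbors` an integer vector (or list);
#'   `graphFamily` and `defaultStart` the family metadata recorded by the
#'   constructors.
#'
#' @examples
#' g <- backwardGraph(4)
#' numNodes(g)
#' outDegree(g)
#' outNeighbors(g, 2)
#'
#' @name MoranGraph-accessors
NULL

#' @rdname MoranGraph-accessors
#' @export
setMethod("numNodes", "MoranGraph", function(x) x@n)

#' @rdname MoranGraph-accessors
#' @export
setMethod("outNeighbors", "MoranGraph", function(x, node) {
  if (missing(node)) return(x@adj)
  x@adj[[node]]
})

#' @rdname MoranGraph-accessors
#' @export
setMethod("outDegree", "MoranGraph", function(x, node) {
  d <- vapply(x@adj, length, integer(1))
  if (missing(node)) d else d[node]
})

#' @rdname MoranGraph-accessors
#' @export
setMethod("graphFamily", "MoranGraph", function(x) x@family)

#' @rdname MoranGraph-accessors
#' @export
setMethod("defaultStart", "MoranGraph", function(x) {
  if (is.na(x@defaultStart)) 1L else x@defaultStart
})

#' @rdname MoranGraph-accessors
#' @export
setMethod("numEdges", "MoranGraph", function(x)
  sum(vapply(x@adj, length, integer(1))))

setMethod("show", "MoranGraph", function(object) {
  fam <- if (is.na(object@family)) "ad hoc" else object@family
  cat(sprintf("MoranGraph: %d nodes, %d directed edges (%s%s)\n",
              object@n, numEdges(object), fam,
              if (isUndirected(object)) ", undirected" else ""))
  if (!is.na(object@defaultStart))
    cat(sprintf("  designated start node: %d\n", object@defaultStart))
})

#' Time-measure accessors
#'
#' Extract the modified-step count, the classic Moran step count, or the real
#' time from a [TimeLedger-class], [ExactResult-class] or (as the Monte-Carlo
#' mean) an [EstimateSummary-class].
#'
#' @param x Object holding time measures.
#' @return A numeric scalar.
#' @name timeMeasures
NULL

#' @rdname timeMeasures
#' @export
setMethod("modifiedSteps", "TimeLedger", function(x) x@modifiedSteps)
#' @rdname timeMeasures
#' @export
setMethod("classicSteps", "TimeLedger", function(x) x@classicSteps)
#' @rdname timeMeasures
#' @export
setMethod("realTime", "TimeLedger", function(x) x@realTime)

#' @rdname timeMeasures
#' @export
setMethod("modifiedSteps", "ExactResult", function(x) x@modifiedSteps)
#' @rdname timeMeasures
#' @export
setMethod("classicSteps", "ExactResult", function(x) x@classicSteps)
#' @rdname timeMeasures
#' @export
setMethod("realTime", "ExactResult", function(x) x@realTime)

#' @rdname timeMeasures
#' @export
setMethod("modifiedSteps", "EstimateSummary", function(x)
  unname(x@means["modifiedSteps"]))
#' @rdname timeMeasures
#' @export
setMethod("classicSteps", "EstimateSummary", function(x)
  unname(x@means["classicSteps"]))
#' @rdname timeMeasures
#' @export
setMethod("realTime", "EstimateSummary", function(x)
  unname(x@means["realTime"]))

setMethod("show", "TimeLedger", function(object) {
  cat(sprintf("TimeLedger: modified %s, classic %s, real %s\n",
              format(object@modifiedSteps), format(object@classicSteps),
              format(object@realTime)))
})

setMethod("show", "ReplicateOutcome", function(object) {
  cat(sprintf("ReplicateOutcome: %s\n", object@outcome))
  show(object@ledger)
})

setMethod("show", "ExactResult", function(object) {
  cat(sprintf(
    "ExactResult (%s arithmetic, %s states):\n", object@arithmetic,
    format(object@statesVisited, big.mark = ",")))
  cat(sprintf("  expected modified steps: %s\n",
              format(object@modifiedSteps)))
  cat(sprintf("  expected classic steps:  %s\n",
              format(object@classicSteps)))
  cat(sprintf("  expected real time:      %s\n", format(object@realTime)))
  if (!anyNA(object@exact))
    cat(sprintf("  exact: %s steps\n", object@exact[["modified"]]))
})

setMethod("show", "EstimateSummary", function(object) {
  cat(sprintf("EstimateSummary: %s engine, %d replicates (seed %s)\n",
              object@engine, object@replicates, format(object@seed)))
  for (nm in names(object@means))
    cat(sprintf("  %-14s %12.4f +/- %.4f\n", nm, object@means[[nm]],
                object@se[[nm]]))
})

setMethod("show", "WorstStartResult", function(object) {
  cat(sprintf(
    "WorstStartResult: T(G) = %s attained at start %d (%d/%d valid starts)\n",
    format(object@value), object@argmax, sum(!is.na(object@perStart)),
    length(object@perStart)))
})

setMethod("show", "CrossoverResult", function(object) {
  cat("CrossoverResult:", object@message, "\n")
  if (!is.na(object@crossover))
    cat(sprintf("  estimated crossover r* = %.3f (CI %.3f - %.3f)\n",
                object@crossover, object@ci[1], object@ci[2]))
})
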