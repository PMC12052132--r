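#' @import methods
NULL

#' Directed population structure for the Moran process
#'
#' A `MoranGraph` stores the population structure of an evolutionary-graph
#' model: `n` sites (nodes) and, for every node, an ordered vector of distinct
#' out-neighbours along which offspring can migrate. Nodes are indexed
#' `1..n`. A graph is *undirected* when every edge is paired with its
#' reverse; it is stored in the same directed representation.
#'
#' Self-loops are invalid (an offspring always migrates to *another* node),
#' duplicate edges are rejected rather than merged, and nodes with
#' out-degree 0 (sinks) are legal: the process treats selecting them as a
#' counted no-op.
#'
#' @slot n Integer, number of nodes (at least 1).
#' @slot adj List of length `n`; element `u` is an integer vector of the
#'   out-neighbours of node `u`.
#' @slot labels Character vector of optional node names (length `n` or 0).
#' @slot family Character scalar naming the generating family (`NA` for ad
#'   hoc graphs).
#' @slot defaultStart Integer scalar, the designated starting node of the
#'   family (`NA` when none is designated).
#'
#' @seealso [moranGraph()], [backwardGraph()], [starGraph()],
#'   [lollipopGraph()], [randomReachableDigraph()]
#' @export
setClass("MoranGraph",
  representation(
    n = "integer",
    adj = "list",
    labels = "character",
    family = "character",
    defaultStart = "integer"
  ),
  prototype(
    labels = character(0),
    family = NA_character_,
    defaultStart = NA_integer_
  )
)

setValidity("MoranGraph", function(object) {
  n <- object@n
  if (length(n) != 1L || is.na(n) || n < 1L)
    return("n must be a single integer >= 1")
  if (length(object@adj) != n)
    return("adj must have one entry per node")
  for (u in seq_len(n)) {
    nb <- object@adj[[u]]
    if (length(nb) == 0L) next
    if (!is.numeric(nb) || anyNA(nb) || any(nb != as.integer(nb)))
      return(sprintf("out-neighbours of node %d must be integers", u))
    if (any(nb < 1L) || any(nb > n))
      return(sprintf("out-neighbours of node %d outside 1..%d", u, n))
    if (any(nb == u))
      return(sprintf("self-loop at node %d", u))
    if (anyDuplicated(nb))
      return(sprintf("duplicate edge out of node %d", u))
  }
  if (length(object@labels) != 0L && length(object@labels) != n)
    return("labels must be empty or of length n")
  if (!is.na(object@defaultStart) &&
      (object@defaultStart < 1L || object@defaultStart > n))
    return("defaultStart outside 1..n")
  TRUE
})

#' Three time measures of one trajectory
#'
#' A `TimeLedger` records the three clocks of a single run: the number of
#' steps of the modified (colonization) process, the number of classic Moran
#' steps among them, and the accrued real time (one classic step at total
#' fitness `F` lasts `1/F` units). Under deterministic real-time accounting
#' at unbounded mutant advantage, `realTime == modifiedSteps / n` holds
#' exactly per trajectory.
#'
#' @slot modifiedSteps Numeric count of modified-process steps (`NA` for the
#'   classic engine, where the modified clock is undefined).
#' @slot classicSteps Numeric count of classic Moran steps.
#' @slot realTime Numeric, continuous real-time units.
#' @export
setClass("TimeLedger",
  representation(
    modifiedSteps = "numeric",
    classicSteps = "numeric",
    realTime = "numeric"
  )
)

setValidity("TimeLedger", function(object) {
  v <- c(object@modifiedSteps, object@classicSteps, object@realTime)
  if (any(!is.na(v) & v < 0)) return("time measures must be nonnegative")
  TRUE
})

#' Outcome of one classic-process replicate
#'
#' @slot outcome Character: `"fixed"`, `"extinct"`, or `"truncated"` (the
#'   step budget ran out before absorption; never silently absorbed).
#' @slot ledger A [TimeLedger-class] for the replicate.
#' @export
setClass("ReplicateOutcome",
  representation(outcome = "character", ledger = "TimeLedger")
)

setValidity("ReplicateOutcome", function(object) {
  if (!object@outcome %in% c("fixed", "extinct", "truncated"))
    return("outcome must be 'fixed', 'extinct' or 'truncated'")
  TRUE
})

#' Exact expected time measures
#'
#' Result of an exact solver: expected values of the three time measures from
#' a given initial mutant set, together with solver diagnostics. In rational
#' mode the `exact` slot carries the values as exact fraction strings
#' (`"num/den"`); the numeric slots are their double projections.
#'
#' @slot modifiedSteps Expected modified-process steps.
#' @slot classicSteps Expected classic Moran steps.
#' @slot realTime Expected real time; always `modifiedSteps / n`.
#' @slot statesVisited Number of non-absorbing states the solver evaluated.
#' @slot arithmetic `"rational"` or `"float"`.
#' @slot exact Named character vector (`modified`, `classic`, `real`) of
#'   exact fraction strings, or `NA` in float mode.
#' @export
setClass("ExactResult",
  representation(
    modifiedSteps = "numeric",
    classicSteps = "numeric",
    realTime = "numeric",
    statesVisited = "numeric",
    arithmetic = "character",
    exact = "character"
  )
)

setValidity("ExactResult", function(object) {
  if (!object@arithmetic %in% c("rational", "float"))
    return("arithmetic must be 'rational' or 'float'")
  if (object@classicSteps > object@modifiedSteps + 1e-9)
    return("expected classic steps cannot exceed expected modified steps")
  TRUE
})

#' Monte-Carlo summary of replicate time measures
#'
#' @slot replicates Integer number of independent replicates.
#' @slot seed Numeric root seed (each replicate uses a derived substream).
#' @slot engine `"colonization"` or `"classic"`.
#' @slot means Named numeric: mean of each time measure over replicates.
#' @slot se Named numeric: standard errors (sample SD / sqrt(replicates)).
#' @slot data Per-replicate data frame (replicate, outcome, modifiedSteps,
#'   classicSteps, realTime).
#' @export
setClass("EstimateSummary",
  representation(
    replicates = "integer",
    seed = "numeric",
    engine = "character",
    means = "numeric",
    se = "numeric",
    data = "data.frame"
  )
)

setValidity("EstimateSummary", function(object) {
  if (object@replicates < 2L) return("at least 2 replicates are required")
  TRUE
})

#' Per-start colonization times and their maximum
#'
#' The colonization time of a graph is the maximum over starting nodes of the
#' expected colonization time from that node; starts that cannot reach every
#' node are excluded (and reported as `NA` in `perStart`).
#'
#' @slot perStart Numeric vector, expected modified steps per starting node.
#' @slot value The maximum over valid starts.
#' @slot argmax Integer node attaining the maximum.
#' @export
setClass("WorstStartResult",
  representation(
    perStart = "numeric",
    value = "numeric",
    argmax = "integer"
  )
)

#' Lollipop initialization crossover scan
#'
#' Per-fitness means of classic Moran steps for the two initializations of
#' the lollipop graph (a single mutant at the path start, versus additionally
#' the whole cluster), and the estimated fitness at which the two curves
#' cross.
#'
#' @slot table Data frame with one row per (r, initialization) pair.
#' @slot crossover Numeric, interpolated crossing of the mean difference
#'   (`NA` when the difference does not change sign on the grid).
#' @slot ci Numeric length-2 bootstrap confidence interval for the crossover.
#' @slot message Character status note (e.g. "no crossover on grid").
#' @export
setClass("CrossoverResult",
  representation(
    table = "data.frame",
    crossover = "numeric",
    ci = "numeric",
    message = "character"
  )
)
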