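#' Forward closure of a node set
#'
#' Nodes reachable from any node in `sources` along directed edges
#' (including the sources themselves). A single initial mutant at `v`
#' colonizes the whole graph if and only if `reachableFrom(g, v)` is all
#' nodes; the exact solvers and the colonization engine require this.
#'
#' @param g A [MoranGraph-class].
#' @param sources Non-empty integer vector of node indices.
#' @return Sorted integer vector of reachable nodes.
#' @examples
#' reachableFrom(totalOrderGraph(5), 1)  # all five nodes
#' reachableFrom(totalOrderGraph(5), 5)  # just the sink
#' @export
reachableFrom <- function(g, sources) {
  sources <- as.integer(sources)
  if (length(sources) == 0L) stop("sources must be non-empty")
  if (any(sources < 1L | sources > g@n)) stop("source node outside 1..n")
  ig <- asIgraph(g)
  reach <- unique(unlist(lapply(sources, function(v)
    as.integer(igraph::subcomponent(ig, v, mode = "out")))))
  sort(reach)
}

#' Graph predicates
#'
#' `isUndirected` tests whether every edge is paired with its reverse;
#' `isRegular` whether all out-degrees are equal (the isothermal class).
#'
#' @param g A [MoranGraph-class].
#' @return Logical scalar.
#' @examples
#' isUndirected(cycleGraph(8))  # TRUE, and isRegular too
#' isRegular(starGraph(5))      # FALSE
#' isUndirected(backwardGraph(5))  # FALSE
#' @export
isUndirected <- function(g) {
  for (u in seq_len(g@n)) {
    for (w in g@adj[[u]]) {
      if (!(u %in% g@adj[[w]])) return(FALSE)
    }
  }
  TRUE
}

#' @rdname isUndirected
#' @export
isRegular <- function(g) {
  d <- outDegree(g)
  length(unique(d)) == 1L
}

#' Convert to an igraph object
#'
#' @param g A [MoranGraph-class].
#' @return An `igraph` directed graph with the same nodes and edges.
#' @export
asIgraph <- function(g) {
  from <- rep(seq_len(g@n), times = vapply(g@adj, length, integer(1)))
  to <- unlist(g@adj, use.names = FALSE)
  if (length(from) == 0L)
    return(igraph::make_empty_graph(n = g@n, directed = TRUE))
  igraph::graph_from_edgelist(cbind(from, to), directed = TRUE) |>
    igraph::add_vertices(max(0L, g@n - max(from, to)))
}

#' Edge-list file input and output
#'
#' The interchange format is a plain TSV of `u<TAB>v` pairs with 0-based
#' node ids, one directed edge per line. Lines starting with `#` are
#' comments; a `# undirected` header expands every line to both directions.
#' `readEdgeList(writeEdgeList(g))` round-trips to an identical graph.
#'
#' @param path File path.
#' @param g A [MoranGraph-class] to write.
#' @param undirected Write the `# undirected` dialect (requires
#'   `isUndirected(g)`; each two-way edge is written once).
#'
#' @return `readEdgeList` returns a [MoranGraph-class]; `writeEdgeList`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeEdgeList(backwardGraph(3), f)
#' readEdgeList(f)
#' @export
readEdgeList <- function(path) {
  lines <- readLines(path)
  undirected <- any(grepl("^#\\s*undirected\\s*$", lines))
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0L) stop("edge-list file has no edges: ", path)
  from <- integer(length(rows))
  to <- integer(length(rows))
  for (i in seq_along(rows)) {
    parts <- strsplit(trimws(lines[rows[i]]), "\\s+")[[1]]
    ok <- length(parts) == 2L && !anyNA(suppressWarnings(as.integer(parts)))
    if (!ok)
      stop(sprintf("malformed edge line %d: '%s'", rows[i], lines[rows[i]]))
    uv <- as.integer(parts)
    if (any(uv < 0L))
      stop(sprintf("negative node id at line %d", rows[i]))
    if (uv[1] == uv[2])
      stop(sprintf("self-loop at line %d: '%s'", rows[i], lines[rows[i]]))
    from[i] <- uv[1]
    to[i] <- uv[2]
  }
  if (undirected) {
    from2 <- c(from, to)
    to2 <- c(to, from)
    from <- from2
    to <- to2
  }
  key <- paste(from, to)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop(sprintf("duplicate edge %d -> %d in %s", from[dup], to[dup], path))
  }
  n <- max(c(from, to)) + 1L
  moranGraph(n, edges = cbind(from + 1L, to + 1L))
}

#' @rdname readEdgeList
#' @export
writeEdgeList <- function(g, path, undirected = FALSE) {
  from <- rep(seq_len(g@n), times = vapply(g@adj, length, integer(1)))
  to <- unlist(g@adj, use.names = FALSE)
  header <- sprintf("# MoranGraph: %d nodes (0-based ids)", g@n)
  if (undirected) {
    if (!isUndirected(g))
      stop("undirected dialect requested for a directed graph")
    keep <- from < to
    from <- from[keep]
    to <- to[keep]
    header <- c(header, "# undirected")
  }
  lines <- c(header, sprintf("%d\t%d", from - 1L, to - 1L))
  writeLines(lines, path)
  invisible(path)
}

# CSR adjacency (0-based) handed to the C++ kernels.
graphCSR <- function(g) {
  deg <- vapply(g@adj, length, integer(1))
  list(
    off = c(0L, cumsum(deg)),
    tgt = as.integer(unlist(g@adj, use.names = FALSE) - 1L)
  )
}

# Shared precondition: the initial mutant set must reach every node.
checkReachesAll <- function(g, init, what = "this solver") {
  init <- sort(unique(as.integer(init)))
  if (length(init) == 0L) stop("initial mutant set must be non-empty")
  if (any(init < 1L | init > g@n)) stop("initial node outside 1..n")
  if (length(reachableFrom(g, init)) != g@n)
    stop(what, " requires every node to be reachable from the initial set")
  init
}
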