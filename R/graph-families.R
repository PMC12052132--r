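#' Construct a MoranGraph from an adjacency list or edge matrix
#'
#' @param n Number of nodes.
#' @param edges Optional two-column matrix of directed edges (from, to),
#'   1-based. Ignored when `adj` is given.
#' @param adj Optional adjacency list (length `n`, 1-based targets).
#' @param labels Optional character vector of node names.
#' @param family,defaultStart Family metadata recorded by the named
#'   constructors; rarely set by hand.
#'
#' @return A validated [MoranGraph-class].
#' @examples
#' moranGraph(2, edges = rbind(c(1, 2), c(2, 1)))  # K2
#' @export
moranGraph <- function(n, edges = NULL, adj = NULL, labels = character(0),
                       family = NA_character_, defaultStart = NA_integer_) {
  n <- as.integer(n)
  if (is.null(adj)) {
    adj <- rep(list(integer(0)), n)
    if (!is.null(edges) && nrow(edges) > 0L) {
      from <- as.integer(edges[, 1L])
      to <- as.integer(edges[, 2L])
      sp <- split(to, factor(from, levels = seq_len(n)))
      adj <- lapply(sp, as.integer)
    }
  } else {
    adj <- lapply(adj, as.integer)
  }
  new("MoranGraph", n = n, adj = unname(adj), labels = labels,
      family = family, defaultStart = as.integer(defaultStart))
}

#' Named graph families
#'
#' Constructors for the population structures studied in the colonization
#' setting. All graphs are returned as [MoranGraph-class] objects with their
#' designated default starting node recorded (`backward`, `total order`,
#' `lollipop`: the path start, node 1; `star`: a leaf; otherwise node 1).
#'
#' * `completeGraph(n)`: all ordered pairs; the well-mixed population.
#' * `cycleGraph(n)`: undirected n-cycle (n >= 3).
#' * `starGraph(n)`: node 1 is the center, two-way edges to nodes `2..n`.
#' * `doubleStarGraph(k)`: two star centers joined by a two-way edge, each
#'   with `k - 1` leaves (`2k` nodes in total).
#' * `totalOrderGraph(n)`: directed edge `i -> j` for every `i < j`; node `n`
#'   is a sink.
#' * `backwardGraph(n)`: directed path `i -> i + 1` plus every one-way edge
#'   going back, `j -> i` for `j > i`. The unique slowest structure for
#'   colonization: its time is exactly `n^2 (n - 1) / 2` steps from node 1.
#' * `lollipopGraph(n)`: `p = round(sqrt(n))` path nodes feeding a complete
#'   undirected cluster of the remaining `n - p` nodes. The last path node
#'   sends a one-way edge to every cluster node (`attach = "all"`, the
#'   default) or just to the first (`attach = "one"`); no edges lead from the
#'   cluster back to the path.
#' * `torusGraph(m)`: 4-regular `m x m` torus lattice (`n = m^2`), a
#'   representative of the regular (isothermal) class.
#'
#' @param n,k,m Size parameters (see above).
#' @param attach Cluster attachment rule for the lollipop path end.
#'
#' @return A [MoranGraph-class].
#' @examples
#' backwardGraph(3)            # deg = (1, 2, 2)
#' outDegree(totalOrderGraph(4))  # 3 2 1 0
#' @name graphFamilies
NULL

#' @rdname graphFamilies
#' @export
completeGraph <- function(n) {
  n <- checkSize(n, 2L, "complete")
  adj <- lapply(seq_len(n), function(u) setdiff(seq_len(n), u))
  moranGraph(n, adj = adj, family = "complete", defaultStart = 1L)
}

#' @rdname graphFamilies
#' @export
cycleGraph <- function(n) {
  n <- checkSize(n, 3L, "cycle")
  adj <- lapply(seq_len(n), function(u) {
    c(if (u == n) 1L else u + 1L, if (u == 1L) n else u - 1L)
  })
  moranGraph(n, adj = adj, family = "cycle", defaultStart = 1L)
}

#' @rdname graphFamilies
#' @export
starGraph <- function(n) {
  n <- checkSize(n, 2L, "star")
  adj <- c(list(seq.int(2L, n)), rep(list(1L), n - 1L))
  moranGraph(n, adj = adj, family = "star",
             defaultStart = 2L)  # a leaf; the expectation is start-invariant
}

#' @rdname graphFamilies
#' @export
doubleStarGraph <- function(k) {
  k <- checkSize(k, 2L, "double_star (k)")
  n <- 2L * k
  # centers 1 and 2; leaves of center 1: 3..k+1, leaves of center 2: k+2..2k
  leaves1 <- if (k > 1L) seq.int(3L, k + 1L) else integer(0)
  leaves2 <- if (k > 1L) seq.int(k + 2L, n) else integer(0)
  adj <- vector("list", n)
  adj[[1L]] <- c(2L, leaves1)
  adj[[2L]] <- c(1L, leaves2)
  for (v in leaves1) adj[[v]] <- 1L
  for (v in leaves2) adj[[v]] <- 2L
  moranGraph(n, adj = adj, family = "double_star", defaultStart = 1L)
}

#' @rdname graphFamilies
#' @export
totalOrderGraph <- function(n) {
  n <- checkSize(n, 2L, "total_order")
  adj <- lapply(seq_len(n), function(u)
    if (u < n) seq.int(u + 1L, n) else integer(0))
  moranGraph(n, adj = adj, family = "total_order", defaultStart = 1L)
}

#' @rdname graphFamilies
#' @export
backwardGraph <- function(n) {
  n <- checkSize(n, 2L, "backward")
  adj <- lapply(seq_len(n), function(u) {
    fwd <- if (u < n) u + 1L else integer(0)
    back <- if (u > 1L) seq_len(u - 1L) else integer(0)
    c(fwd, back)
  })
  moranGraph(n, adj = adj, family = "backward", defaultStart = 1L)
}

#' @rdname graphFamilies
#' @export
lollipopGraph <- function(n, attach = c("all", "one")) {
  attach <- match.arg(attach)
  n <- checkSize(n, 4L, "lollipop")
  p <- as.integer(round(sqrt(n)))
  cluster <- seq.int(p + 1L, n)
  adj <- vector("list", n)
  for (u in seq_len(p - 1L)) adj[[u]] <- u + 1L
  adj[[p]] <- if (attach == "all") cluster else cluster[1L]
  for (u in cluster) adj[[u]] <- setdiff(cluster, u)
  moranGraph(n, adj = adj, family = "lollipop", defaultStart = 1L)
}

#' @rdname graphFamilies
#' @export
torusGraph <- function(m) {
  m <- checkSize(m, 3L, "torus (side)")
  n <- m * m
  idx <- function(i, j) ((i - 1L) %% m) * m + ((j - 1L) %% m) + 1L
  adj <- vector("list", n)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      adj[[idx(i, j)]] <- c(idx(i - 1L, j), idx(i + 1L, j),
                            idx(i, j - 1L), idx(i, j + 1L))
    }
  }
  moranGraph(n, adj = adj, family = "torus", defaultStart = 1L)
}

#' Random reachable digraph fixtures
#'
#' Samples every ordered pair (or unordered pair, when `undirected = TRUE`)
#' independently with probability `edgeProb`, then rejection-resamples until
#' every node is reachable from node 1. Deterministic given `seed`.
#'
#' @param n Number of nodes (>= 2).
#' @param edgeProb Edge probability in (0, 1].
#' @param seed Integer seed; the same seed always returns the same graph.
#' @param undirected Sample a two-way (undirected) graph instead.
#' @param maxTries Number of rejection rounds before giving up (a failure
#'   signals that `edgeProb` is too small for reachability at this `n`).
#'
#' @return A [MoranGraph-class] in which all nodes are reachable from node 1.
#' @examples
#' g <- randomReachableDigraph(8, 0.4, seed = 1)
#' length(reachableFrom(g, 1)) == 8
#' @export
randomReachableDigraph <- function(n, edgeProb, seed, undirected = FALSE,
                                   maxTries = 1000L) {
  n <- checkSize(n, 2L, "random")
  stopifnot(edgeProb > 0, edgeProb <= 1)
  rng <- localRNG(seed)
  for (try in seq_len(maxTries)) {
    if (undirected) {
      pairs <- utils::combn(n, 2L)
      keep <- rng$unif(ncol(pairs)) < edgeProb
      from <- c(pairs[1L, keep], pairs[2L, keep])
      to <- c(pairs[2L, keep], pairs[1L, keep])
    } else {
      from <- rep(seq_len(n), each = n)
      to <- rep(seq_len(n), times = n)
      off <- from != to
      from <- from[off]
      to <- to[off]
      keep <- rng$unif(length(from)) < edgeProb
      from <- from[keep]
      to <- to[keep]
    }
    g <- moranGraph(n, edges = cbind(from, to),
                    family = if (undirected) "random_undirected" else "random",
                    defaultStart = 1L)
    if (length(reachableFrom(g, 1L)) == n) return(g)
  }
  stop("randomReachableDigraph: no reachable graph in ", maxTries,
       " attempts; increase edgeProb")
}

#' Build a graph family from a flat specification
#'
#' Dispatcher used by the command-line interface and the experiment runners.
#' Family names follow the CLI spelling: `complete`, `cycle`, `star`,
#' `double-star`, `total-order`, `backward`, `lollipop`, `torus`, `random`
#' (underscores are accepted too).
#'
#' @param family Family name.
#' @param n Number of nodes (for `double-star` it must be even and `k = n/2`
#'   is used; for `torus`, `n` must be a perfect square).
#' @param edgeProb,seed,undirected Passed to [randomReachableDigraph()] for
#'   `family = "random"`.
#'
#' @return A [MoranGraph-class].
#' @examples
#' buildFamily("backward", 5)
#' @export
buildFamily <- function(family, n, edgeProb = 0.4, seed = 1L,
                        undirected = FALSE) {
  key <- gsub("-", "_", tolower(family))
  switch(key,
    complete = completeGraph(n),
    cycle = cycleGraph(n),
    star = starGraph(n),
    double_star = {
      if (n %% 2L != 0L) stop("double-star needs an even node count")
      doubleStarGraph(n %/% 2L)
    },
    total_order = totalOrderGraph(n),
    backward = backwardGraph(n),
    lollipop = lollipopGraph(n),
    torus = {
      m <- as.integer(round(sqrt(n)))
      if (m * m != n) stop("torus needs a square node count")
      torusGraph(m)
    },
    random = randomReachableDigraph(n, edgeProb, seed,
                                    undirected = undirected),
    stop("unknown graph family: ", family)
  )
}

# -- internal helpers --------------------------------------------------------

checkSize <- function(n, minimum, what) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < minimum)
    stop(sprintf("%s graphs need size >= %d", what, minimum))
  n
}

# Seed-local RNG: leaves the caller's .Random.seed untouched.
localRNG <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
  restore()
  env$unif <- function(k) {
    prev <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    assign(".Random.seed", env$state, envir = globalenv())
    x <- stats::runif(k)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(prev)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", prev, envir = globalenv())
    }
    x
  }
  env
}
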