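#' Exact expected colonization times (monotone dynamic program)
#'
#' Computes the expected number of modified-process steps (and classic steps
#' and real time) until fixation at r -> infinity, by a memoized recursion
#' over the mutant sets reachable from the initial state. Because mutant
#' sets only ever grow, the state graph is acyclic and each state is solved
#' once: with per-step gain probabilities
#' `p(M -> M + w) = (1/n) * sum_{u in M, w in N(u)} 1/deg(u)`,
#' the expected modified steps satisfy
#' `E[M] = 1/p_leave(M) + sum_w P(w | leave) E[M + w]`;
#' classic steps add `(|M|/n) / p_leave(M)` per state and real time is
#' `E[M] / n`.
#'
#' Arithmetic is exact rational (GMP, arbitrary precision) by default for
#' `n <= 12` and available for any graph; float is the default above, where
#' the state count rather than the arithmetic is the limit.
#'
#' @param g A [MoranGraph-class] with at most 64 nodes.
#' @param init Initial mutant node(s); must reach every node.
#' @param stateCap Refuse (with the count reached) beyond this many states.
#' @param arithmetic `"auto"` (rational for `n <= 12`), `"rational"` or
#'   `"float"`.
#'
#' @return An [ExactResult-class].
#' @examples
#' colonizationExact(backwardGraph(3), init = 1)  # exactly 9 steps
#' colonizationExact(cycleGraph(6), init = 1)     # exactly 30 = n(n-1)
#' @export
colonizationExact <- function(g, init = defaultStart(g), stateCap = 2e6,
                              arithmetic = c("auto", "rational", "float")) {
  arithmetic <- match.arg(arithmetic)
  if (arithmetic == "auto")
    arithmetic <- if (g@n <= 12L) "rational" else "float"
  init <- checkReachesAll(g, init, "colonizationExact")
  if (g@n > 64L) stop("the bitmask solver requires n <= 64")
  csr <- graphCSR(g)
  res <- cpp_exact_dp(g@n, csr$off, csr$tgt, init - 1L, stateCap,
                      arithmetic == "rational")
  makeExactResult(res, arithmetic)
}

#' Brute-force subset oracle for the colonization time
#'
#' Independent check on [colonizationExact()]: enumerates every mutant
#' superset of the initial set over the full subset lattice (no reachability
#' pruning, no recursion) in inclusion order. Exact-rational results must
#' agree bit-for-bit with the dynamic program, float results to 1e-9
#' relative. Restricted to `n <= 14`.
#'
#' The float mode runs in plain R; the rational mode shares the GMP rational
#' kernel with the dynamic program but none of its state enumeration.
#'
#' @inheritParams colonizationExact
#' @return An [ExactResult-class].
#' @examples
#' colonizationExactBruteForce(completeGraph(2), init = 1)  # 2 steps
#' @export
colonizationExactBruteForce <- function(g, init = defaultStart(g),
                                        arithmetic = c("float", "rational")) {
  arithmetic <- match.arg(arithmetic)
  init <- checkReachesAll(g, init, "the brute-force solver")
  if (g@n > 14L) stop("the brute-force subset solver requires n <= 14")
  if (arithmetic == "rational") {
    csr <- graphCSR(g)
    res <- cpp_exact_brute(g@n, csr$off, csr$tgt, init - 1L, TRUE)
    return(makeExactResult(res, "rational"))
  }
  bruteForceFloatR(g, init)
}

# Pure-R float enumeration over all supersets of init, in decreasing mask
# order (adding a node always increases the mask).
bruteForceFloatR <- function(g, init) {
  n <- g@n
  bits <- 2L^(seq_len(n) - 1L)
  full <- sum(bits)
  imask <- sum(bits[init])
  if (imask == full)
    return(makeExactResult(list(modified = 0, classic = 0, real = 0,
                                states = 0, exact = NULL), "float"))
  Emod <- rep(NA_real_, full + 1L)
  Ecls <- rep(NA_real_, full + 1L)
  Emod[full + 1L] <- 0
  Ecls[full + 1L] <- 0
  deg <- outDegree(g)
  states <- 0
  for (mask in seq.int(full - 1L, imask)) {
    if (bitwAnd(mask, imask) != imask) next
    mut <- bitwAnd(mask, bits) > 0L
    q <- numeric(n)
    for (u in which(mut)) {
      if (deg[u] == 0L) next
      nb <- g@adj[[u]]
      res <- nb[!mut[nb]]
      q[res] <- q[res] + 1 / deg[u]
    }
    gains <- which(q > 0)
    Q <- sum(q[gains])
    nxt <- mask + bits[gains] + 1L
    Emod[mask + 1L] <- (n + sum(q[gains] * Emod[nxt])) / Q
    Ecls[mask + 1L] <- (sum(mut) + sum(q[gains] * Ecls[nxt])) / Q
    states <- states + 1
  }
  makeExactResult(list(modified = Emod[imask + 1L], classic = Ecls[imask + 1L],
                       real = Emod[imask + 1L] / n, states = states,
                       exact = NULL), "float")
}

makeExactResult <- function(res, arithmetic) {
  ex <- if (is.null(res$exact)) {
    c(modified = NA_character_, classic = NA_character_, real = NA_character_)
  } else {
    stats::setNames(res$exact, c("modified", "classic", "real"))
  }
  new("ExactResult", modifiedSteps = res$modified, classicSteps = res$classic,
      realTime = res$real, statesVisited = res$states,
      arithmetic = arithmetic, exact = ex)
}

#' Closed-form colonization times for named families
#'
#' Expected modified steps from the designated start, as explicit formulas
#' (each validated against the exact solvers in the test suite):
#' backward `n^2 (n-1) / 2`; complete `2 (n-1) H(n-1)`;
#' cycle `n (n-1)`; star `n (n-1) H(n-1)` (identical for center and leaf
#' starts), with `H(k)` the k-th harmonic number, computed by direct
#' summation.
#'
#' @param family One of `"backward"`, `"complete"`, `"cycle"`, `"star"`.
#' @param n Number of nodes (>= 2; may be a vector).
#' @return Numeric vector of expected modified steps.
#' @examples
#' closedFormTime("backward", 10)  # 450
#' closedFormTime("star", 3)       # 9
#' @export
closedFormTime <- function(family, n) {
  family <- match.arg(family, c("backward", "complete", "cycle", "star"))
  if (any(n < 2)) stop("closed forms need n >= 2")
  vapply(n, function(nn) {
    switch(family,
      backward = nn^2 * (nn - 1) / 2,
      complete = 2 * (nn - 1) * harmonicNumber(nn - 1),
      cycle = nn * (nn - 1),
      star = nn * (nn - 1) * harmonicNumber(nn - 1)
    )
  }, numeric(1))
}

#' Harmonic numbers by direct summation
#'
#' @param k Nonnegative integer(s).
#' @return `H(k) = 1 + 1/2 + ... + 1/k` (0 for `k = 0`).
#' @export
harmonicNumber <- function(k) {
  vapply(k, function(kk) if (kk < 1) 0 else sum(1 / seq_len(kk)), numeric(1))
}

#' Symmetry-reduced exact solver for the star graph
#'
#' Stage recursion over the states (center status, number of mutant leaves):
#' `O(n)` states, so exact far beyond the subset solvers. Center and leaf
#' starts give the identical expectation.
#'
#' @param n Number of nodes (>= 2).
#' @return A data frame with one row per start class (`center`, `leaf`) and
#'   the three expected time measures.
#' @examples
#' starExact(3)  # 9 modified steps from either start
#' @export
starExact <- function(n) {
  if (n < 2) stop("star needs n >= 2")
  # E1[l + 1]: expectation from (center mutant, l mutant leaves)
  E1m <- numeric(n)   # modified
  E1c <- numeric(n)   # classic
  # absorbing at l = n - 1
  if (n >= 2) {
    for (l in seq.int(n - 2, 0)) {
      # only the center can gain: p_leave = (1/n) (n-1-l)/(n-1)
      stage <- n * (n - 1) / (n - 1 - l)
      E1m[l + 1] <- stage + E1m[l + 2]
      E1c[l + 1] <- ((1 + l) / n) * stage + E1c[l + 2]
    }
  }
  # (center resident, l >= 1 mutant leaves): p_leave = l/n, gains the center
  center <- c(E1m[1], E1c[1])
  leaf <- c(n / 1 + E1m[2], 1 + E1c[2])
  data.frame(
    start = c("center", "leaf"),
    modifiedSteps = c(center[1], leaf[1]),
    classicSteps = c(center[2], leaf[2]),
    realTime = c(center[1], leaf[1]) / n
  )
}

#' Symmetry-reduced exact solver for the double star
#'
#' Dynamic program over the lumped states (center 1 status, center 2 status,
#' mutant leaves on each side): `O(k^2)` states for the `2k`-node double
#' star, exact far beyond brute force. Covers both start classes.
#'
#' @param k Leaves-plus-center size of each star half (>= 2); the graph has
#'   `2k` nodes.
#' @return A data frame with one row per start class (`center`, `leaf`) and
#'   the three expected time measures.
#' @examples
#' doubleStarExact(2)
#' @export
doubleStarExact <- function(k) {
  if (k < 2) stop("double star needs k >= 2")
  n <- 2L * k
  L <- k - 1L  # leaves per side
  # E[c1, c2, l1, l2] indexed as arrays [c1+1, c2+1, l1+1, l2+1]
  dims <- c(2L, 2L, L + 1L, L + 1L)
  Em <- array(NA_real_, dims)
  Ec <- array(NA_real_, dims)
  Em[2, 2, L + 1, L + 1] <- 0
  Ec[2, 2, L + 1, L + 1] <- 0
  # per-coordinate descending loops: every gain increases one coordinate
  for (l1 in seq.int(L, 0)) {
    for (l2 in seq.int(L, 0)) {
      for (c1 in c(1L, 0L)) {
        for (c2 in c(1L, 0L)) {
          total <- c1 + c2 + l1 + l2
          if (total == 0L || total == n) next
          # gain rates scaled by n (q = n * p)
          qc1 <- if (c1 == 0L) l1 + c2 / k else 0
          qc2 <- if (c2 == 0L) l2 + c1 / k else 0
          ql1 <- if (c1 == 1L && l1 < L) (L - l1) / k else 0
          ql2 <- if (c2 == 1L && l2 < L) (L - l2) / k else 0
          Q <- qc1 + qc2 + ql1 + ql2
          sm <- qc1 * zeroIfNA(Em[2, c2 + 1, l1 + 1, l2 + 1], qc1) +
            qc2 * zeroIfNA(Em[c1 + 1, 2, l1 + 1, l2 + 1], qc2) +
            ql1 * zeroIfNA(Em[c1 + 1, c2 + 1, l1 + 2, l2 + 1], ql1) +
            ql2 * zeroIfNA(Em[c1 + 1, c2 + 1, l1 + 1, l2 + 2], ql2)
          sc <- qc1 * zeroIfNA(Ec[2, c2 + 1, l1 + 1, l2 + 1], qc1) +
            qc2 * zeroIfNA(Ec[c1 + 1, 2, l1 + 1, l2 + 1], qc2) +
            ql1 * zeroIfNA(Ec[c1 + 1, c2 + 1, l1 + 2, l2 + 1], ql1) +
            ql2 * zeroIfNA(Ec[c1 + 1, c2 + 1, l1 + 1, l2 + 2], ql2)
          Em[c1 + 1, c2 + 1, l1 + 1, l2 + 1] <- (n + sm) / Q
          Ec[c1 + 1, c2 + 1, l1 + 1, l2 + 1] <- (total + sc) / Q
        }
      }
    }
  }
  center <- c(Em[2, 1, 1, 1], Ec[2, 1, 1, 1])
  leaf <- c(Em[1, 1, 2, 1], Ec[1, 1, 2, 1])
  data.frame(
    start = c("center", "leaf"),
    modifiedSteps = c(center[1], leaf[1]),
    classicSteps = c(center[2], leaf[2]),
    realTime = c(center[1], leaf[1]) / n
  )
}

# A gain with positive rate always points at a solved state; NA can only be
# reached with rate 0, where 0 * NA must count as 0.
zeroIfNA <- function(x, rate) {
  if (rate == 0 || is.na(x)) 0 else x
}

#' Symmetry-reduced exact solver for the lollipop graph
#'
#' Dynamic program over the lumped states (path prefix length, cluster
#' mutant count): the path colonizes strictly left to right and the cluster
#' nodes are exchangeable, giving `O(sqrt(n) * n)` states. Reports both
#' initializations of the classic-steps paradox: a single mutant at the path
#' start (`"path"`), and the path start plus the whole cluster
#' (`"path+cluster"`).
#'
#' @param n Number of nodes (>= 4).
#' @return A data frame with one row per initialization and the three
#'   expected time measures.
#' @examples
#' lollipopExact(9)
#' @export
lollipopExact <- function(n) {
  if (n < 4) stop("lollipop needs n >= 4")
  p <- as.integer(round(sqrt(n)))
  s <- n - p  # cluster size (>= 2 for n >= 4)
  # E[q, c + 1]: q path nodes and c cluster nodes mutant
  Em <- matrix(NA_real_, nrow = p, ncol = s + 1L)
  Ec <- matrix(NA_real_, nrow = p, ncol = s + 1L)
  Em[p, s + 1L] <- 0
  Ec[p, s + 1L] <- 0
  cdeg <- s - 1L  # degree of a cluster node
  for (q in seq.int(p, 1L)) {
    for (cc in seq.int(s, 0L)) {
      if (q == p && cc == s) next
      # gain rates scaled by n
      qpath <- if (q < p) 1 else 0
      qclus <- 0
      if (q == p) qclus <- qclus + (s - cc) / s          # path end seeds
      if (cc > 0L && cdeg > 0L)
        qclus <- qclus + cc * (s - cc) / cdeg            # within cluster
      Q <- qpath + qclus
      sm <- 0
      sc <- 0
      if (qpath > 0) {
        sm <- sm + qpath * Em[q + 1L, cc + 1L]
        sc <- sc + qpath * Ec[q + 1L, cc + 1L]
      }
      if (qclus > 0) {
        sm <- sm + qclus * Em[q, cc + 2L]
        sc <- sc + qclus * Ec[q, cc + 2L]
      }
      Em[q, cc + 1L] <- (n + sm) / Q
      Ec[q, cc + 1L] <- ((q + cc) + sc) / Q
    }
  }
  pathOnly <- c(Em[1L, 1L], Ec[1L, 1L])
  pathCluster <- c(Em[1L, s + 1L], Ec[1L, s + 1L])
  data.frame(
    init = c("path", "path+cluster"),
    modifiedSteps = c(pathOnly[1], pathCluster[1]),
    classicSteps = c(pathOnly[2], pathCluster[2]),
    realTime = c(pathOnly[1], pathCluster[1]) / n
  )
}

#' Worst-start colonization time T(G)
#'
#' Solves the exact colonization time from every starting node and reports
#' the maximum, `T(G) = max_v T(G, v)`. Starts that cannot reach all nodes
#' are excluded (reported as `NA`) rather than assigned infinite time,
#' matching the standing reachability assumption.
#'
#' @param g A [MoranGraph-class].
#' @param stateCap Per-start state cap for [colonizationExact()].
#' @return A [WorstStartResult-class].
#' @examples
#' worstStartTime(backwardGraph(5))  # 50 steps, attained at node 1
#' @export
worstStartTime <- function(g, stateCap = 2e6) {
  n <- g@n
  perStart <- rep(NA_real_, n)
  for (v in seq_len(n)) {
    if (length(reachableFrom(g, v)) != n) next
    perStart[v] <- modifiedSteps(
      colonizationExact(g, init = v, stateCap = stateCap,
                        arithmetic = "float"))
  }
  if (all(is.na(perStart)))
    stop("no starting node reaches every node")
  new("WorstStartResult", perStart = perStart,
      value = max(perStart, na.rm = TRUE),
      argmax = which.max(perStart))
}

#' Finite-fitness absorbing-chain solver
#'
#' Solves the classic Moran Birth-death process with relative fitness
#' `r > 0` exactly, over the full lattice of mutant sets (an absorbing
#' Markov chain with `2^n` states; the finite-r chain is not monotone, so
#' nothing smaller is available in general). Returns the unconditional
#' expected number of classic steps, the accrued real time, and the fixation
#' probability from the given initial set. Restricted to `n <= 12`.
#'
#' @param g A [MoranGraph-class] with `n <= 12`.
#' @param init Initial mutant node(s).
#' @param r Relative mutant fitness (finite, > 0).
#' @return A list with `expectedClassicSteps`, `expectedRealTime` and
#'   `fixationProb`.
#' @examples
#' absorptionExactClassic(completeGraph(3), init = 1, r = 1)$fixationProb
#' # 1/3: neutral fixation probability
#' @export
absorptionExactClassic <- function(g, init, r) {
  n <- g@n
  if (n > 12L) stop("the finite-r solver enumerates 2^n states; n <= 12")
  if (!is.finite(r) || r <= 0)
    stop("r must be finite and positive (use the exact colonization solvers ",
         "for r = Inf)")
  init <- sort(unique(as.integer(init)))
  if (length(init) == 0L) stop("initial mutant set must be non-empty")
  bits <- 2L^(seq_len(n) - 1L)
  full <- sum(bits)
  imask <- sum(bits[init])
  if (imask == full)
    return(list(expectedClassicSteps = 0, expectedRealTime = 0,
                fixationProb = 1))

  deg <- outDegree(g)
  ulist <- rep(seq_len(n), times = deg)
  wlist <- unlist(g@adj, use.names = FALSE)
  udeg <- deg[ulist]

  transient <- seq_len(full - 1L)  # masks 1 .. 2^n - 2
  il <- vector("list", full - 1L)
  jl <- vector("list", full - 1L)
  xl <- vector("list", full - 1L)
  b <- numeric(full - 1L)
  stepReward <- rep(1, full - 1L)
  timeReward <- numeric(full - 1L)

  for (mask in transient) {
    mut <- bitwAnd(mask, bits) > 0L
    m <- sum(mut)
    Fit <- r * m + (n - m)
    timeReward[mask] <- 1 / Fit
    mu <- mut[ulist]
    mw <- mut[wlist]
    wgt <- ifelse(mu, r, 1) / (Fit * udeg)
    gain <- mu & !mw
    loss <- !mu & mw
    move <- gain | loss
    if (!any(move)) next
    target <- integer(sum(move))
    target[gain[move]] <- mask + bits[wlist[gain]]
    target[loss[move]] <- mask - bits[wlist[loss]]
    x <- wgt[move]
    agg <- rowsum(x, target)
    tgtMask <- as.integer(rownames(agg))
    isFull <- tgtMask == full
    isEmpty <- tgtMask == 0L
    b[mask] <- sum(agg[isFull])
    keep <- !isFull & !isEmpty
    # self-transition = 1 - all moving probability
    il[[mask]] <- rep(mask, sum(keep) + 1L)
    jl[[mask]] <- c(tgtMask[keep], mask)
    xl[[mask]] <- c(agg[keep], 1 - sum(agg))
  }

  Q <- Matrix::sparseMatrix(i = unlist(il), j = unlist(jl), x = unlist(xl),
                            dims = c(full - 1L, full - 1L))
  A <- Matrix::Diagonal(full - 1L) - Q
  tsteps <- Matrix::solve(A, stepReward)
  ttime <- Matrix::solve(A, timeReward)
  h <- Matrix::solve(A, b)
  list(
    expectedClassicSteps = as.numeric(tsteps[imask]),
    expectedRealTime = as.numeric(ttime[imask]),
    fixationProb = as.numeric(h[imask])
  )
}
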