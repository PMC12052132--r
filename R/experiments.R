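#' Scaling curves of colonization time over population size
#'
#' For each family and each size on the grid, obtains the expected time
#' measures either exactly (symmetry-reduced solver or validated closed form
#' where one exists, the monotone DP where the state space permits) or by
#' seeded simulation, and fits a log-log slope per family over the top half
#' of the size grid (least squares; small-n transients suppressed). A point
#' for which no exact route fits inside `stateCap` and that would exceed the
#' simulation budget is emitted with status `"skipped"`, never dropped.
#'
#' @param families Character vector of family names (CLI spelling, see
#'   [buildFamily()]).
#' @param nGrid Strictly increasing integer vector of population sizes.
#' @param replicates Replicates per simulated point (>= 100).
#' @param seed Integer root seed; every output row records the seed that
#'   produced it.
#' @param preferExact Use exact solvers where available (default `TRUE`).
#' @param stateCap State cap for DP-based exact points.
#'
#' @return A data frame with columns family, n, method, status, the three
#'   time-measure means, their standard errors (0 for exact points) and
#'   seed; the per-family log-log slopes of the modified-step curve are
#'   attached as `attr(, "slopes")`.
#' @examples
#' sc <- runScaling("backward", c(4, 8, 16, 32), seed = 1)
#' attr(sc, "slopes")  # close to 3: the cubic law
#' @export
runScaling <- function(families, nGrid, replicates = 1000L, seed = 1L,
                       preferExact = TRUE, stateCap = 2e6) {
  nGrid <- as.integer(nGrid)
  if (any(diff(nGrid) <= 0)) stop("nGrid must be strictly increasing")
  replicates <- as.integer(replicates)
  if (replicates < 100L) stop("use at least 100 replicates per point")
  rows <- list()
  for (fam in families) {
    for (i in seq_along(nGrid)) {
      n <- nGrid[i]
      ptSeed <- as.integer((seed * 1000L + match(fam, families) * 100L + i) %%
                             .Machine$integer.max)
      row <- scalingPoint(fam, n, replicates, ptSeed, preferExact, stateCap)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  slopes <- vapply(unique(out$family), function(fam) {
    sub <- out[out$family == fam & out$status == "ok", , drop = FALSE]
    if (nrow(sub) < 2L) return(NA_real_)
    fitLoglogSlope(sub$n, sub$modifiedSteps)
  }, numeric(1))
  attr(out, "slopes") <- slopes
  out
}

scalingPoint <- function(fam, n, replicates, seed, preferExact, stateCap) {
  key <- gsub("-", "_", tolower(fam))
  row <- data.frame(
    family = key, n = n, method = NA_character_, status = "ok",
    modifiedSteps = NA_real_, classicSteps = NA_real_, realTime = NA_real_,
    modifiedSE = NA_real_, classicSE = NA_real_, realSE = NA_real_,
    seed = seed
  )
  exact <- NULL
  if (preferExact) exact <- tryExactFamily(key, n, stateCap)
  if (!is.null(exact)) {
    row$method <- "exact"
    row$modifiedSteps <- exact[["modified"]]
    row$classicSteps <- exact[["classic"]]
    row$realTime <- exact[["real"]]
    row$modifiedSE <- 0
    row$classicSE <- 0
    row$realSE <- 0
    return(row)
  }
  g <- tryCatch(buildFamily(key, n, seed = seed), error = function(e) NULL)
  if (is.null(g)) {
    row$method <- "none"
    row$status <- "skipped"
    return(row)
  }
  est <- estimateTimes(g, engine = "colonization", replicates = replicates,
                       seed = seed)
  row$method <- "simulated"
  row$modifiedSteps <- est@means[["modifiedSteps"]]
  row$classicSteps <- est@means[["classicSteps"]]
  row$realTime <- est@means[["realTime"]]
  row$modifiedSE <- est@se[["modifiedSteps"]]
  row$classicSE <- est@se[["classicSteps"]]
  row$realSE <- est@se[["realTime"]]
  row
}

# Exact route per family from the designated start, where one exists at this
# size; NULL means "simulate instead".
tryExactFamily <- function(key, n, stateCap) {
  res <- switch(key,
    backward = ,
    cycle = ,
    complete = ,
    star = {
      mod <- closedFormTime(key, n)
      ex <- if (key %in% c("backward", "cycle") && n <= 64) {
        colonizationExact(buildFamily(key, n), stateCap = stateCap,
                          arithmetic = "float")
      } else {
        NULL
      }
      cls <- if (!is.null(ex)) classicSteps(ex) else exactClassicClosed(key, n)
      c(modified = mod, classic = cls, real = mod / n)
    },
    double_star = {
      if (n %% 2L != 0L) return(NULL)
      ds <- doubleStarExact(n %/% 2L)
      row <- ds[ds$start == "center", ]
      c(modified = row$modifiedSteps, classic = row$classicSteps,
        real = row$realTime)
    },
    lollipop = {
      lp <- lollipopExact(n)
      row <- lp[lp$init == "path", ]
      c(modified = row$modifiedSteps, classic = row$classicSteps,
        real = row$realTime)
    },
    total_order = {
      if (n > 20L || 2^(n - 1) > stateCap) return(NULL)
      ex <- colonizationExact(totalOrderGraph(n), stateCap = stateCap,
                              arithmetic = "float")
      c(modified = modifiedSteps(ex), classic = classicSteps(ex),
        real = realTime(ex))
    },
    NULL
  )
  res
}

# Expected classic steps for the star/complete stage chains (same stage
# decomposition as the closed forms: |M|/n of the stage's steps are classic).
exactClassicClosed <- function(key, n) {
  if (key == "star") {
    st <- starExact(n)
    return(st$classicSteps[st$start == "leaf"])
  }
  if (key == "complete") {
    m <- seq_len(n - 1)
    return(sum((m / n) * n * (n - 1) / (m * (n - m))))
  }
  NA_real_
}

#' Least-squares log-log slope over the top half of a size grid
#'
#' @param n Sizes.
#' @param y Positive values.
#' @param topFraction Fraction of the largest sizes used (default 0.5).
#' @return The fitted slope of `log(y) ~ log(n)`.
#' @export
fitLoglogSlope <- function(n, y, topFraction = 0.5) {
  keep <- rank(n) >= length(n) - ceiling(length(n) * topFraction) + 1L
  fit <- stats::lm(log(y[keep]) ~ log(n[keep]))
  unname(stats::coef(fit)[2])
}

#' Extremal-bound audit over random digraphs and named families
#'
#' For each size `n`, draws seeded random reachable digraphs (plus an
#' undirected sample) and takes every named family at that size, solves the
#' exact colonization time from every valid start, and audits the bounds:
#' every `T(G, v)` must lie between `n H(n-1)` (the per-stage gain
#' probability never exceeds `|M|/n`) and the cubic ceiling
#' `n^3/2 - n^2/2`, which is attained with equality exactly by the backward
#' graph from its path start. Undirected graphs are additionally compared
#' against `4 n^2 sqrt(n)`; because that bound is asymptotic, violations are
#' reported in the table rather than raised as errors.
#'
#' @param nList Integer vector of sizes (each <= 12: exact-solver regime).
#' @param graphsPerN Random digraphs per size (an undirected sample of half
#'   that many is added).
#' @param seed Integer seed; the audit is rerun-identical.
#' @param edgeProb Edge probability of the random samples.
#'
#' @return A list with `table` (one row per graph and valid start: the exact
#'   time, each bound, and pass flags) and `summary` (per-n verdicts, the
#'   maximal ratio to the cubic bound and the graph attaining it).
#' @examples
#' audit <- runBoundAudit(5, graphsPerN = 5, seed = 7)
#' all(audit$table$upperOk)
#' @export
runBoundAudit <- function(nList, graphsPerN = 50L, seed = 1L,
                          edgeProb = 0.4) {
  rows <- list()
  for (n in as.integer(nList)) {
    if (n > 12L) stop("the bound audit uses the exact solvers; n <= 12")
    graphs <- auditGraphSet(n, graphsPerN, seed, edgeProb)
    for (gi in seq_along(graphs)) {
      g <- graphs[[gi]]
      name <- names(graphs)[gi]
      ws <- tryCatch(worstStartTime(g), error = function(e) NULL)
      if (is.null(ws)) next
      undirected <- isUndirected(g)
      for (v in which(!is.na(ws@perStart))) {
        tval <- ws@perStart[v]
        upper <- n^3 / 2 - n^2 / 2
        lower <- n * harmonicNumber(n - 1)
        undBound <- 4 * n^2 * sqrt(n)
        rows[[length(rows) + 1L]] <- data.frame(
          n = n, graph = name, start = v, undirected = undirected,
          T = tval, lower = lower, upper = upper,
          lowerOk = tval >= lower - 1e-9,
          upperOk = tval <= upper + 1e-9,
          tight = abs(tval - upper) < 1e-6,
          undirectedBound = undBound,
          undirectedOk = if (undirected) tval <= undBound else NA
        )
      }
    }
  }
  table <- do.call(rbind, rows)
  summary <- lapply(split(table, table$n), function(sub) {
    top <- sub[which.max(sub$T), ]
    list(
      n = top$n,
      allUpperOk = all(sub$upperOk),
      allLowerOk = all(sub$lowerOk),
      undirectedAllOk = all(sub$undirectedOk[sub$undirected]),
      maxRatioToCubic = max(sub$T) / top$upper[1],
      extremalGraph = top$graph,
      extremalStart = top$start,
      tightGraphs = unique(sub$graph[sub$tight])
    )
  })
  list(table = table, summary = summary)
}

auditGraphSet <- function(n, graphsPerN, seed, edgeProb) {
  graphs <- list()
  fams <- c("complete", "star", "total_order", "backward")
  if (n >= 3L) fams <- c(fams, "cycle")
  if (n >= 4L) fams <- c(fams, "lollipop")
  if (n %% 2L == 0L && n >= 4L) fams <- c(fams, "double_star")
  for (fam in fams)
    graphs[[fam]] <- buildFamily(fam, n)
  for (i in seq_len(graphsPerN))
    graphs[[sprintf("random_%03d", i)]] <-
      randomReachableDigraph(n, edgeProb, seed = seed * 10000L + i)
  for (i in seq_len(max(1L, graphsPerN %/% 2L)))
    graphs[[sprintf("random_und_%03d", i)]] <-
      randomReachableDigraph(n, min(1, edgeProb * 1.5),
                             seed = seed * 20000L + i, undirected = TRUE)
  graphs
}

#' Lollipop initialization paradox: classic-step crossover scan
#'
#' On the lollipop graph, compares the expected number of classic Moran
#' steps under two initializations: a single mutant at the path start
#' (`"path"`) versus the path start plus every cluster node
#' (`"path+cluster"`, a strict superset). For small fitness the superset
#' finishes sooner; beyond a crossover fitness `r*` it takes *more* classic
#' steps, because cluster mutants absorb reproduction events that no longer
#' advance the front. The crossover is located by the sign change of the
#' mean difference (linear interpolation between adjacent grid points) with
#' a bootstrap confidence interval; if the difference never changes sign the
#' result says so.
#'
#' At the published scale (`n = 1600`, `r` spanning 2..10, >= 1000
#' replicates per point) this is an hours-long run and is the long-form
#' reproduction; the machinery is identical at any smaller `n`.
#'
#' @param n Lollipop size (>= 16 for a meaningful path/cluster split).
#' @param rGrid Increasing fitness grid inside (1, Inf).
#' @param replicates Replicates per (r, initialization) point (>= 100;
#'   >= 1000 for the headline reproduction).
#' @param seed Integer root seed.
#' @param maxSteps Classic-engine budget; truncated replicates invalidate
#'   their point (status column) rather than biasing it.
#' @param bootstrap Bootstrap resamples for the crossover CI.
#'
#' @return A [CrossoverResult-class].
#' @examples
#' \donttest{
#' cr <- runLollipopCrossover(64, rGrid = c(2, 4, 8), replicates = 200,
#'                            seed = 1)
#' cr@table
#' }
#' @export
runLollipopCrossover <- function(n, rGrid, replicates = 1000L, seed = 1L,
                                 maxSteps = 1e9, bootstrap = 200L) {
  n <- as.integer(n)
  if (n < 16L) stop("use n >= 16 for a meaningful path/cluster split")
  rGrid <- sort(as.numeric(rGrid))
  if (any(rGrid <= 1)) stop("rGrid must lie in (1, Inf)")
  replicates <- as.integer(replicates)
  if (replicates < 100L) stop("use at least 100 replicates per point")
  g <- lollipopGraph(n)
  p <- as.integer(round(sqrt(n)))
  inits <- list(path = 1L, `path+cluster` = c(1L, seq.int(p + 1L, n)))

  rows <- list()
  reps <- list()  # per (r, init) classic-step vectors for the bootstrap
  for (ri in seq_along(rGrid)) {
    r <- rGrid[ri]
    for (ini in names(inits)) {
      ptSeed <- seed * 1000L + ri * 10L + match(ini, names(inits))
      est <- suppressWarnings(
        estimateTimes(g, init = inits[[ini]], engine = "classic", r = r,
                      replicates = replicates, seed = ptSeed,
                      maxSteps = maxSteps))
      trunc <- sum(est@data$outcome == "truncated")
      rows[[length(rows) + 1L]] <- data.frame(
        r = r, init = ini, replicates = replicates,
        truncated = trunc,
        status = if (trunc > 0) "invalid" else "ok",
        meanClassicSteps = est@means[["classicSteps"]],
        seClassicSteps = est@se[["classicSteps"]],
        seed = ptSeed
      )
      reps[[paste(ri, ini)]] <-
        est@data$classicSteps[est@data$outcome != "truncated"]
    }
  }
  table <- do.call(rbind, rows)

  ok <- tapply(table$status == "ok", table$r, all)
  validR <- as.numeric(names(ok))[ok]
  dmean <- vapply(seq_along(rGrid), function(ri) {
    mean(reps[[paste(ri, "path")]]) - mean(reps[[paste(ri, "path+cluster")]])
  }, numeric(1))
  usable <- rGrid %in% validR

  crossFromDiff <- function(rv, dv) {
    s <- sign(dv)
    flip <- which(s[-1] * s[-length(s)] < 0)
    if (length(flip) == 0L) return(NA_real_)
    i <- flip[1]
    rv[i] + (rv[i + 1] - rv[i]) * (0 - dv[i]) / (dv[i + 1] - dv[i])
  }
  crossover <- crossFromDiff(rGrid[usable], dmean[usable])

  ci <- c(NA_real_, NA_real_)
  if (!is.na(crossover) && bootstrap > 0L) {
    rng <- localRNG(seed + 777L)
    boots <- numeric(0)
    for (bi in seq_len(bootstrap)) {
      dv <- vapply(which(usable), function(ri) {
        a <- reps[[paste(ri, "path")]]
        b <- reps[[paste(ri, "path+cluster")]]
        ia <- ceiling(rng$unif(length(a)) * length(a))
        ib <- ceiling(rng$unif(length(b)) * length(b))
        mean(a[ia]) - mean(b[ib])
      }, numeric(1))
      boots <- c(boots, crossFromDiff(rGrid[usable], dv))
    }
    boots <- boots[!is.na(boots)]
    if (length(boots) >= 10L)
      ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  }

  msg <- if (is.na(crossover)) {
    "no crossover on grid"
  } else {
    sprintf("crossover located on the r grid at r* = %.3f", crossover)
  }
  new("CrossoverResult", table = table, crossover = crossover, ci = ci,
      message = msg)
}
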