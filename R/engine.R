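#' Simulate the colonization (r -> infinity) process
#'
#' Runs the modified Moran Birth-death process in which only mutants
#' reproduce: each step picks a uniformly random node; a mutant pick
#' reproduces onto a uniform out-neighbour (a wasted reproduction when the
#' neighbour is already a mutant, a counted no-op when the node is a sink),
#' a resident pick changes nothing. The run ends at fixation, which is
#' certain when the initial set reaches every node.
#'
#' All three clocks are recorded: modified steps (every step), classic steps
#' (mutant picks only) and real time. With `realTimeMode = "deterministic"`
#' the real time is `modifiedSteps / n` exactly, per trajectory, matching the
#' divide-by-n correspondence between colonization steps and real duration;
#' `"sampled"` instead accrues an exponential draw with mean `1/|M|` per
#' classic step (the continuous-time reading with unit-rate mutant clocks).
#'
#' `skipIdle` draws the geometric run of idle (resident-pick) steps in one
#' shot; mutant picks are never skipped, so the ledger is distributionally
#' identical to the step-by-step simulation.
#'
#' @param g A [MoranGraph-class].
#' @param init Initial mutant node(s); defaults to the family's designated
#'   start. Must reach every node.
#' @param seed Integer seed.
#' @param skipIdle Compress idle runs (default `TRUE`).
#' @param realTimeMode `"deterministic"` or `"sampled"`.
#'
#' @return A [TimeLedger-class].
#' @examples
#' runColonization(cycleGraph(4), init = 1, seed = 1)
#' @export
runColonization <- function(g, init = defaultStart(g), seed = 1L,
                            skipIdle = TRUE,
                            realTimeMode = c("deterministic", "sampled")) {
  realTimeMode <- match.arg(realTimeMode)
  init <- checkReachesAll(g, init, "the colonization engine")
  csr <- graphCSR(g)
  m <- cpp_sim_colonization(g@n, csr$off, csr$tgt, init - 1L, 1L,
                            as.double(seed), skipIdle,
                            realTimeMode == "sampled")
  new("TimeLedger", modifiedSteps = m[1, 1], classicSteps = m[1, 2],
      realTime = m[1, 3])
}

#' Simulate the classic Moran Birth-death process
#'
#' Each step selects an individual proportional to fitness (mutants `r`,
#' residents 1; for `r = Inf` selection is uniform over mutants only, with
#' the mutants-have-fitness-1 convention for total fitness), and the
#' offspring replaces a uniform out-neighbour; reproduction onto an
#' individual of the same type is a wasted step, and selecting a sink is a
#' counted no-op. Real time accrues `1/F` per step with
#' `F = r |M| + (n - |M|)` (or `|M|` at `r = Inf`).
#'
#' @param g A [MoranGraph-class].
#' @param init Initial mutant node(s); non-empty. For `r = Inf` the set must
#'   reach every node.
#' @param r Relative mutant fitness (> 0), or `Inf`.
#' @param seed Integer seed.
#' @param maxSteps Step budget; running out yields outcome `"truncated"`,
#'   never a silently absorbed run.
#'
#' @return A [ReplicateOutcome-class] whose ledger reports classic steps and
#'   real time (`modifiedSteps` is `NA`: that clock belongs to the modified
#'   process).
#' @examples
#' runClassic(completeGraph(2), init = 1, r = 1, seed = 7)
#' @export
runClassic <- function(g, init = defaultStart(g), r, seed = 1L,
                       maxSteps = 1e9) {
  if (r <= 0) stop("r must be positive (possibly Inf)")
  if (is.infinite(r)) {
    init <- checkReachesAll(g, init, "the classic engine at r = Inf")
  } else {
    init <- sort(unique(as.integer(init)))
    if (length(init) == 0L) stop("initial mutant set must be non-empty")
    if (any(init < 1L | init > g@n)) stop("initial node outside 1..n")
  }
  csr <- graphCSR(g)
  m <- cpp_sim_classic(g@n, csr$off, csr$tgt, init - 1L, as.double(r), 1L,
                       as.double(seed), as.double(maxSteps))
  code <- m[1, 1]
  outcome <- if (code == 1) "fixed" else if (code == 0) "extinct" else
    "truncated"
  new("ReplicateOutcome", outcome = outcome,
      ledger = new("TimeLedger", modifiedSteps = NA_real_,
                   classicSteps = m[1, 2], realTime = m[1, 3]))
}

#' Monte-Carlo estimation of expected time measures
#'
#' Runs independent replicates of either engine, each on its own substream
#' derived from the root seed (replicate i is reproducible in isolation),
#' and reports the mean and standard error of every time measure. Results
#' are bit-for-bit reproducible given `(seed, replicates)`.
#'
#' Truncated classic replicates are excluded from the means and flagged in
#' the returned data; their count is reported via a warning.
#'
#' @param g A [MoranGraph-class].
#' @param init Initial mutant node(s); defaults to the designated start.
#' @param engine `"colonization"` or `"classic"`.
#' @param replicates Number of replicates (>= 2).
#' @param seed Integer root seed.
#' @param r Fitness for the classic engine (ignored otherwise).
#' @param skipIdle,realTimeMode Colonization-engine options, see
#'   [runColonization()].
#' @param maxSteps Classic-engine step budget.
#'
#' @return An [EstimateSummary-class]; slot `data` holds the per-replicate
#'   ledger.
#' @examples
#' est <- estimateTimes(backwardGraph(4), replicates = 500, seed = 1)
#' modifiedSteps(est)  # close to the exact 4^2 * 3 / 2 = 24
#' @export
estimateTimes <- function(g, init = defaultStart(g),
                          engine = c("colonization", "classic"),
                          replicates = 1000L, seed = 1L, r = Inf,
                          skipIdle = TRUE,
                          realTimeMode = c("deterministic", "sampled"),
                          maxSteps = 1e9) {
  engine <- match.arg(engine)
  realTimeMode <- match.arg(realTimeMode)
  replicates <- as.integer(replicates)
  if (replicates < 2L) stop("at least 2 replicates are required")
  csr <- graphCSR(g)

  if (engine == "colonization") {
    init <- checkReachesAll(g, init, "the colonization engine")
    m <- cpp_sim_colonization(g@n, csr$off, csr$tgt, init - 1L, replicates,
                              as.double(seed), skipIdle,
                              realTimeMode == "sampled")
    dat <- data.frame(
      replicate = seq_len(replicates),
      outcome = "fixed",
      modifiedSteps = m[, 1],
      classicSteps = m[, 2],
      realTime = m[, 3]
    )
  } else {
    if (r <= 0) stop("r must be positive (possibly Inf)")
    if (is.infinite(r)) {
      init <- checkReachesAll(g, init, "the classic engine at r = Inf")
    } else {
      init <- sort(unique(as.integer(init)))
    }
    m <- cpp_sim_classic(g@n, csr$off, csr$tgt, init - 1L, as.double(r),
                         replicates, as.double(seed), as.double(maxSteps))
    outcome <- rep("truncated", replicates)
    outcome[m[, 1] == 1] <- "fixed"
    outcome[m[, 1] == 0] <- "extinct"
    dat <- data.frame(
      replicate = seq_len(replicates),
      outcome = outcome,
      modifiedSteps = NA_real_,
      classicSteps = m[, 2],
      realTime = m[, 3]
    )
    ntrunc <- sum(outcome == "truncated")
    if (ntrunc > 0)
      warning(ntrunc, " replicate(s) truncated at maxSteps; ",
              "excluded from the means")
  }

  used <- dat[dat$outcome != "truncated", , drop = FALSE]
  measure <- c("modifiedSteps", "classicSteps", "realTime")
  means <- vapply(measure, function(k) mean(used[[k]]), numeric(1))
  se <- vapply(measure, function(k) {
    stats::sd(used[[k]]) / sqrt(nrow(used))
  }, numeric(1))
  new("EstimateSummary", replicates = replicates, seed = as.double(seed),
      engine = engine, means = means, se = se, data = dat)
}
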