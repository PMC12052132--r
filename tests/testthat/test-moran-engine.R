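test_that("two-node colonization behaves like a fair geometric race", {
  # from one mutant on K2: success per step = pick the mutant (1/2), so the
  # modified-step count is geometric with mean 2
  est <- estimateTimes(completeGraph(2), replicates = 10000, seed = 1)
  expect_lt(abs(zscore(est, "modifiedSteps", 2)), 3)
  # every step that counts as classic grew the mutant set here
  expect_true(all(est@data$classicSteps <= est@data$modifiedSteps))
})

test_that("deterministic real time equals modified steps over n, per replicate", {
  for (g in list(cycleGraph(5), backwardGraph(6), lollipopGraph(9))) {
    est <- estimateTimes(g, replicates = 200, seed = 3)
    expect_identical(est@data$realTime * numNodes(g), est@data$modifiedSteps)
  }
  # sampled mode does not satisfy the pathwise identity, only the expectation
  ests <- estimateTimes(cycleGraph(5), replicates = 5000, seed = 4,
                        realTimeMode = "sampled")
  expect_false(all(ests@data$realTime * 5 == ests@data$modifiedSteps))
  exact <- realTime(colonizationExact(cycleGraph(5), arithmetic = "float"))
  expect_lt(abs(zscore(ests, "realTime", exact)), 4)
})

test_that("identical seeds replay identical ledgers, different seeds differ", {
  g <- backwardGraph(8)
  a <- estimateTimes(g, replicates = 50, seed = 99)
  b <- estimateTimes(g, replicates = 50, seed = 99)
  expect_identical(a@data, b@data)
  c <- estimateTimes(g, replicates = 50, seed = 100)
  expect_false(identical(a@data, c@data))
  # substreams: the first replicates of a longer run reproduce a shorter one
  d <- estimateTimes(g, replicates = 25, seed = 99)
  expect_identical(a@data[1:25, ], d@data)
})

test_that("idle-run compression leaves all three measures distributionally intact", {
  g <- starGraph(8)
  on <- estimateTimes(g, replicates = 10000, seed = 5, skipIdle = TRUE)
  off <- estimateTimes(g, replicates = 10000, seed = 6, skipIdle = FALSE)
  for (k in c("modifiedSteps", "classicSteps", "realTime")) {
    se <- sqrt(on@se[[k]]^2 + off@se[[k]]^2)
    expect_lt(abs(on@means[[k]] - off@means[[k]]), 4 * se)
  }
})

test_that("classic engine matches neutral symmetry and the r = Inf guarantees", {
  # K2 at r = 1: fixation probability 1/2
  est <- estimateTimes(completeGraph(2), engine = "classic", r = 1,
                       replicates = 10000, seed = 7)
  p <- mean(est@data$outcome == "fixed")
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 10000))

  # r = Inf: fixation is certain, and classic steps match the exact solver
  g <- lollipopGraph(16)
  esti <- estimateTimes(g, engine = "classic", r = Inf, replicates = 5000,
                        seed = 8)
  expect_true(all(esti@data$outcome == "fixed"))
  exact <- colonizationExact(g, arithmetic = "float")
  expect_lt(abs(zscore(esti, "classicSteps", classicSteps(exact))), 3)
  expect_lt(abs(zscore(esti, "realTime", realTime(exact))), 3)

  # finite r on a graph whose path start cannot be overwritten: always fixes,
  # in finitely many steps that agree with the absorbing-chain solver
  g9 <- lollipopGraph(9)
  est9 <- estimateTimes(g9, engine = "classic", r = 5, replicates = 10000,
                        seed = 9)
  expect_true(all(est9@data$outcome == "fixed"))
  ab <- absorptionExactClassic(g9, init = 1, r = 5)
  expect_equal(ab$fixationProb, 1, tolerance = 1e-9)
  expect_lt(abs(zscore(est9, "classicSteps", ab$expectedClassicSteps)), 3)
})

test_that("running out of the step budget is reported as truncation", {
  out <- runClassic(cycleGraph(6), init = 1, r = 2, seed = 1, maxSteps = 3)
  expect_identical(out@outcome, "truncated")
  expect_equal(classicSteps(out@ledger), 3)
  # truncated replicates are excluded from means, with a warning; a budget
  # of 3 steps only leaves room for early extinctions
  expect_warning(
    est <- estimateTimes(cycleGraph(6), engine = "classic", r = 2,
                         replicates = 50, seed = 1, maxSteps = 3),
    "truncated")
  expect_true(all(est@data$outcome %in% c("truncated", "extinct")))
  expect_gt(sum(est@data$outcome == "truncated"), 0)
  used <- est@data$outcome != "truncated"
  expect_equal(est@means[["classicSteps"]],
               mean(est@data$classicSteps[used]))
})

test_that("star colonization is start-independent in expectation", {
  g <- starGraph(50)
  leaf <- estimateTimes(g, init = 2, replicates = 10000, seed = 10)
  center <- estimateTimes(g, init = 1, replicates = 10000, seed = 11)
  se <- sqrt(leaf@se[["modifiedSteps"]]^2 + center@se[["modifiedSteps"]]^2)
  expect_lt(abs(modifiedSteps(leaf) - modifiedSteps(center)), 3 * se)
})

test_that("engine preconditions are enforced before simulating", {
  # start that cannot reach all nodes is rejected up front
  expect_error(runColonization(totalOrderGraph(4), init = 4, seed = 1),
               "reachable")
  expect_error(estimateTimes(cycleGraph(4), replicates = 1), "replicates")
  expect_error(runClassic(cycleGraph(4), init = 1, r = -1, seed = 1),
               "positive")
  # degenerate but legal: SE from two replicates
  est <- estimateTimes(completeGraph(2), replicates = 2, seed = 1)
  expect_true(is.finite(est@se[["modifiedSteps"]]))
})
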