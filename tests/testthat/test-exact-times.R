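test_that("hand-derived small-graph expectations are reproduced exactly", {
  # backward(3) from the path start: stages of 3 and 6 expected steps
  ex <- colonizationExact(backwardGraph(3))
  expect_identical(ex@exact[["modified"]], "9")
  expect_equal(modifiedSteps(ex), 9)
  # K2: one stage, success probability 1/2
  expect_equal(modifiedSteps(colonizationExact(completeGraph(2))), 2)
  # cycle(6): every stage leaves with probability 1/n
  expect_equal(modifiedSteps(colonizationExact(cycleGraph(6))), 30)
  # real time is always modified / n, bit-for-bit
  for (g in list(backwardGraph(5), starGraph(6), totalOrderGraph(6))) {
    e <- colonizationExact(g, arithmetic = "float")
    expect_identical(realTime(e), modifiedSteps(e) / numNodes(g))
    expect_lte(classicSteps(e), modifiedSteps(e))
  }
})

test_that("rational results agree with an independent arbitrary-precision oracle", {
  # frozen fraction strings from a Python fractions dynamic program
  to6 <- colonizationExact(totalOrderGraph(6), arithmetic = "rational")
  expect_identical(to6@exact[["modified"]], frozenOracle$total_order6$modified)
  expect_identical(to6@exact[["classic"]], frozenOracle$total_order6$classic)

  s5 <- colonizationExact(starGraph(5), init = 2, arithmetic = "rational")
  expect_identical(s5@exact[["modified"]], frozenOracle$star5_leaf$modified)
  expect_identical(s5@exact[["classic"]], frozenOracle$star5_leaf$classic)

  l9 <- colonizationExact(lollipopGraph(9), init = 1, arithmetic = "rational")
  expect_identical(l9@exact[["modified"]], frozenOracle$lollipop9_path$modified)
  expect_identical(l9@exact[["classic"]], frozenOracle$lollipop9_path$classic)
})

test_that("dynamic program and brute-force subset solver are interchangeable", {
  for (g in familySet(9)) {
    dpF <- colonizationExact(g, arithmetic = "float")
    bfF <- colonizationExactBruteForce(g, arithmetic = "float")
    expect_equal(modifiedSteps(dpF), modifiedSteps(bfF), tolerance = 1e-9)
    expect_equal(classicSteps(dpF), classicSteps(bfF), tolerance = 1e-9)
    dpR <- colonizationExact(g, arithmetic = "rational")
    bfR <- colonizationExactBruteForce(g, arithmetic = "rational")
    expect_identical(dpR@exact, bfR@exact)
  }
  for (seed in 1:10) {
    g <- randomReachableDigraph(8, 0.35, seed = seed)
    expect_identical(
      colonizationExact(g, arithmetic = "rational")@exact,
      colonizationExactBruteForce(g, arithmetic = "rational")@exact)
  }
})

test_that("closed forms match the solvers across the validation range", {
  for (n in 3:12) {
    expect_equal(closedFormTime("backward", n),
                 modifiedSteps(colonizationExact(backwardGraph(n),
                                                 arithmetic = "float")),
                 tolerance = 1e-12)
    expect_equal(closedFormTime("cycle", n),
                 modifiedSteps(colonizationExact(cycleGraph(n),
                                                 arithmetic = "float")),
                 tolerance = 1e-12)
    expect_equal(closedFormTime("complete", n),
                 modifiedSteps(colonizationExact(completeGraph(n),
                                                 arithmetic = "float")),
                 tolerance = 1e-12)
    expect_equal(closedFormTime("star", n),
                 modifiedSteps(colonizationExact(starGraph(n), init = 2,
                                                 arithmetic = "float")),
                 tolerance = 1e-12)
  }
  # instantiations: backward(10) = 450; C3 = K3 = 6; star(3) = 9
  expect_equal(closedFormTime("backward", 10), 450)
  expect_equal(closedFormTime("cycle", 3), 6)
  expect_equal(closedFormTime("complete", 3), 6)
  expect_equal(closedFormTime("star", 3), 9)
})

test_that("symmetry-reduced star and double-star solvers match brute force", {
  # star: reduced recursion = closed form = subset DP; both starts identical
  for (n in c(3, 6, 10)) {
    st <- starExact(n)
    expect_equal(st$modifiedSteps[1], st$modifiedSteps[2], tolerance = 1e-12)
    expect_equal(st$modifiedSteps[1], closedFormTime("star", n),
                 tolerance = 1e-12)
    full <- colonizationExact(starGraph(n), init = 2, arithmetic = "float")
    expect_equal(st$classicSteps[st$start == "leaf"], classicSteps(full),
                 tolerance = 1e-9)
  }
  # double star at k = 2 (4-node case) and k = 5 against the subset DP
  for (k in c(2, 5)) {
    ds <- doubleStarExact(k)
    g <- doubleStarGraph(k)
    expect_equal(ds$modifiedSteps[ds$start == "center"],
                 modifiedSteps(colonizationExact(g, init = 1,
                                                 arithmetic = "float")),
                 tolerance = 1e-9)
    expect_equal(ds$modifiedSteps[ds$start == "leaf"],
                 modifiedSteps(colonizationExact(g, init = 3,
                                                 arithmetic = "float")),
                 tolerance = 1e-9)
    expect_equal(ds$classicSteps[ds$start == "leaf"],
                 classicSteps(colonizationExact(g, init = 3,
                                                arithmetic = "float")),
                 tolerance = 1e-9)
  }
  # growing the double star never speeds it up
  tk <- vapply(2:50, function(k)
    doubleStarExact(k)$modifiedSteps[1], numeric(1))
  expect_true(all(diff(tk) > 0))
})

test_that("lollipop reduced solver matches the subset DP and scales as n^1.5", {
  for (n in c(9, 12)) {
    lp <- lollipopExact(n)
    g <- lollipopGraph(n)
    p <- round(sqrt(n))
    expect_equal(lp$modifiedSteps[lp$init == "path"],
                 modifiedSteps(colonizationExact(g, init = 1,
                                                 arithmetic = "float")),
                 tolerance = 1e-9)
    expect_equal(lp$classicSteps[lp$init == "path"],
                 classicSteps(colonizationExact(g, init = 1,
                                                arithmetic = "float")),
                 tolerance = 1e-9)
    expect_equal(lp$modifiedSteps[lp$init == "path+cluster"],
                 modifiedSteps(colonizationExact(g, init = c(1, (p + 1):n),
                                                 arithmetic = "float")),
                 tolerance = 1e-9)
  }
  # colonization steps grow like n^1.5 (real time like sqrt(n))
  grid <- c(100, 400, 1600, 6400)
  tvals <- vapply(grid, function(n)
    lollipopExact(n)$modifiedSteps[1], numeric(1))
  slope <- fitLoglogSlope(grid, tvals, topFraction = 1)
  expect_gt(slope, 1.35)
  expect_lt(slope, 1.65)
  rvals <- vapply(grid, function(n) lollipopExact(n)$realTime[1], numeric(1))
  expect_equal(rvals, tvals / grid, tolerance = 1e-12)
})

test_that("worst-start scan finds the extremal start and respects exclusions", {
  ws <- worstStartTime(backwardGraph(5))
  expect_equal(ws@value, 50)  # (1/2) 125 - (1/2) 25
  expect_identical(ws@argmax, 1L)
  expect_true(all(diff(ws@perStart) < 0))  # later starts are strictly faster

  # star: every start gives the same expectation
  ws2 <- worstStartTime(starGraph(6))
  expect_equal(max(ws2@perStart) - min(ws2@perStart), 0, tolerance = 1e-9)

  # K3: symmetric
  ws3 <- worstStartTime(completeGraph(3))
  expect_equal(unname(ws3@perStart), rep(6, 3))

  # total order: only node 1 reaches everything
  ws4 <- worstStartTime(totalOrderGraph(5))
  expect_identical(which(!is.na(ws4@perStart)), 1L)
})

test_that("finite-fitness absorbing-chain solver reproduces known probabilities", {
  expect_equal(absorptionExactClassic(completeGraph(2), 1, 1)$fixationProb,
               0.5, tolerance = 1e-9)
  expect_equal(absorptionExactClassic(completeGraph(3), 1, 1)$fixationProb,
               1 / 3, tolerance = 1e-9)
  # well-mixed Moran: rho = (1 - 1/r) / (1 - 1/r^n)
  r <- 2
  n <- 6
  rho <- (1 - 1 / r) / (1 - 1 / r^n)
  expect_equal(absorptionExactClassic(completeGraph(n), 1, r)$fixationProb,
               rho, tolerance = 1e-9)
  # lollipop(9): the path start has no in-edges, fixation is certain
  ab <- absorptionExactClassic(lollipopGraph(9), 1, 4)
  expect_equal(ab$fixationProb, 1, tolerance = 1e-9)
  expect_gt(ab$expectedClassicSteps, 0)
  expect_error(absorptionExactClassic(completeGraph(3), 1, Inf), "finite")
})

test_that("state caps and size limits refuse loudly instead of degrading", {
  expect_error(colonizationExact(completeGraph(10), stateCap = 100), "cap")
  expect_error(colonizationExactBruteForce(completeGraph(15)), "n <= 14")
  expect_error(absorptionExactClassic(completeGraph(13), 1, 2), "n <= 12")
  expect_error(colonizationExact(totalOrderGraph(4), init = 4), "reachable")
})
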