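test_that("scaling runner recovers the known growth laws", {
  sc <- runScaling(c("backward", "cycle", "complete"), c(8, 16, 32, 64),
                   replicates = 200, seed = 1)
  slopes <- attr(sc, "slopes")
  expect_gt(slopes[["backward"]], 2.8)
  expect_lt(slopes[["backward"]], 3.2)
  expect_gt(slopes[["cycle"]], 1.9)
  expect_lt(slopes[["cycle"]], 2.1)
  # complete graph: mean / (n ln n) stable across the grid
  sub <- sc[sc$family == "complete", ]
  ratio <- sub$modifiedSteps / (sub$n * log(sub$n))
  expect_lt(max(ratio) / min(ratio), 1.3)
  # every row records its seed and a status
  expect_true(all(sc$status == "ok"))
  expect_true(all(is.finite(sc$seed)))
})

test_that("simulated scaling points agree with exact ones where both exist", {
  ex <- runScaling("double-star", c(8, 16), seed = 2)
  sim <- runScaling("double-star", c(8, 16), seed = 2, preferExact = FALSE,
                    replicates = 4000)
  expect_identical(unique(ex$method), "exact")
  expect_identical(unique(sim$method), "simulated")
  for (i in 1:2) {
    expect_lt(abs(sim$modifiedSteps[i] - ex$modifiedSteps[i]),
              3 * sim$modifiedSE[i])
  }
})

test_that("torus colonization respects the quadratic regular-graph ceiling", {
  # For regular graphs real time is at most n, i.e. at most n^2 modified
  # steps. The cycle attains the quadratic law; the two-dimensional torus
  # grows as a ball (frontier ~ sqrt(|M|)) and sits well below it, around
  # n^1.5.
  grid <- c(36, 100, 196, 400)
  sc <- runScaling("torus", grid, replicates = 400, seed = 3)
  expect_true(all(sc$modifiedSteps + 3 * sc$modifiedSE < grid^2))
  slope <- attr(sc, "slopes")[["torus"]]
  expect_gt(slope, 1.3)
  expect_lt(slope, 2.2)
})

test_that("bound audit certifies the sandwich and the unique tight graph", {
  audit <- runBoundAudit(6, graphsPerN = 10, seed = 5)
  s <- audit$summary[["6"]]
  expect_true(s$allUpperOk)
  expect_true(s$allLowerOk)
  expect_true(s$undirectedAllOk)
  expect_identical(s$extremalGraph, "backward")
  expect_identical(s$tightGraphs, "backward")
  expect_equal(s$maxRatioToCubic, 1, tolerance = 1e-9)
  # rerun-identical
  audit2 <- runBoundAudit(6, graphsPerN = 10, seed = 5)
  expect_identical(audit$table, audit2$table)
  # the degenerate two-node audit: both bounds are tight on K2
  a2 <- runBoundAudit(2, graphsPerN = 2, seed = 1)
  expect_true(all(abs(a2$table$T - 2) < 1e-9))
})

test_that("crossover scan flags the initialization paradox at high fitness", {
  cr <- runLollipopCrossover(100, rGrid = c(2, 5, 10), replicates = 400,
                             seed = 6)
  tab <- cr@table
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$status == "ok"))
  top <- tab[tab$r == 10, ]
  # at large r the superset initialization needs more classic steps
  expect_gt(top$meanClassicSteps[top$init == "path+cluster"],
            top$meanClassicSteps[top$init == "path"])
  # the report is self-consistent about whether a sign change exists
  d <- with(tab, tapply(meanClassicSteps, list(r, init), mean))
  signs <- sign(d[, "path"] - d[, "path+cluster"])
  if (any(signs[-1] * signs[-length(signs)] < 0)) {
    expect_false(is.na(cr@crossover))
    expect_gte(cr@crossover, 2)
    expect_lte(cr@crossover, 10)
  } else {
    expect_true(is.na(cr@crossover))
    expect_match(cr@message, "no crossover")
  }
})

test_that("command-line interface drives the solvers and reports usage errors", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "exact.csv")
  status <- moranCLI(c("exact", "--graph", "backward", "--n", "10",
                       "--start", "1", "--out", out))
  expect_identical(status, 0L)
  got <- utils::read.csv(out)
  expect_equal(got$modified_steps, 450)
  expect_identical(got$arithmetic, "rational")

  # worst-start table
  out2 <- file.path(dir, "worst.csv")
  expect_identical(moranCLI(c("exact", "--graph", "star", "--n", "5",
                              "--start", "worst", "--out", out2)), 0L)
  expect_equal(nrow(utils::read.csv(out2)), 5L)

  # simulation CSV with the documented columns
  out3 <- file.path(dir, "sim.csv")
  expect_identical(
    suppressMessages(moranCLI(c("simulate", "--graph", "cycle", "--n", "8",
                                "--replicates", "120", "--seed", "4",
                                "--out", out3))), 0L)
  sim <- utils::read.csv(out3)
  expect_identical(names(sim), c("replicate", "outcome", "modifiedSteps",
                                 "classicSteps", "realTime"))
  expect_equal(nrow(sim), 120L)

  # config file supplies flags, explicit flags win
  cfg <- file.path(dir, "cfg")
  writeLines(c("graph=backward", "n=4", "out=ignored.csv"), cfg)
  out4 <- file.path(dir, "cfg.csv")
  expect_identical(moranCLI(c("exact", "--config", cfg, "--out", out4)), 0L)
  expect_equal(utils::read.csv(out4)$modified_steps, 24)

  # failures exit nonzero with usage text
  expect_message(expect_identical(moranCLI(c("frobnicate")), 2L), "unknown")
  expect_message(expect_identical(moranCLI(character(0)), 2L), "usage")
  expect_message(
    expect_identical(moranCLI(c("exact", "--graph", "backward")), 2L),
    "error")
})
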