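Package: MoranColonize
Title: Colonization Times of the Moran Birth-Death Process on Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Moran Birth-death process in the colonization limit,
    where an invading type with unbounded fitness advantage spreads over an
    otherwise empty spatially structured environment represented by a directed
    graph. Provides validated constructors for the standard population
    structures (complete, cycle, star, double star, total order, backward,
    lollipop, torus, random reachable digraphs), seeded stochastic simulation
    of both the modified colonization process and the classic Birth-death
    process with simultaneous accounting of modified steps, classic steps and
    real time, exact expected-time solvers (a monotone-state dynamic program
    with optional exact rational arithmetic, a brute-force subset oracle, a
    finite-fitness absorbing-chain solver, closed forms, and symmetry-reduced
    recursions for star, double star and lollipop graphs), and experiment
    runners for scaling curves, extremal-bound audits and the lollipop
    initialization paradox.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Matrix,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
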