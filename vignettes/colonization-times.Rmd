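---
title: "Colonization times on graphs: model, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colonization times on graphs: model, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MoranColonize)
```

## The model

The classic Moran Birth-death process on a directed graph $G$ with $n$
nodes repeats one update: an individual is selected for reproduction with
probability proportional to its fitness, and its offspring replaces a
uniformly random out-neighbour. Mutants carry relative fitness $r$,
residents fitness 1. This package is about the *colonization limit*
$r \to \infty$, in which residents never reproduce — biologically, an
invading species spreading over an otherwise empty, spatially structured
environment (a resident "individual" is then just an empty site). In that
limit the natural object is the **modified Moran process**: each step picks
a uniformly random node; if it is a mutant it reproduces onto a uniform
out-neighbour, otherwise nothing happens. Idle steps are counted on
purpose — that is what makes the step count proportional to real duration
(below).

Starting from a mutant set $M_0$ whose nodes jointly reach every node, the
mutant set only ever grows and fixates with probability one. The
**colonization time** $T(G, v)$ is the expected number of modified steps
from a single mutant at $v$ until fixation, and
$T(G) = \max_v T(G, v)$ over starts that reach every node (others are
excluded, not assigned infinite time).

### Three clocks

Every run is scored on three simultaneous clocks:

* **modified steps** — all steps, idle ones included;
* **classic steps** — the mutant-pick steps, i.e. the steps the classic
  process would count;
* **real time** — one classic step at total population fitness $F$ lasts
  $1/F$ units. At $r \to \infty$ with the mutants-have-fitness-1
  convention, $F = |M|$.

In expectation, real time equals modified steps divided by $n$. The
default ("deterministic") accounting makes this an identity per
trajectory, by accruing $1/n$ per modified step: a state with $|M|$
mutants takes $n/|M|$ modified steps on average and contributes $1/|M|$
real time per classic step either way, so the two accountings have the
same expectation, but the deterministic one carries the divide-by-$n$
correspondence pathwise. The alternative `realTimeMode = "sampled"` draws
an exponential with mean $1/|M|$ per classic step, matching the
continuous-time picture of unit-rate exponential reproduction clocks.

The classic engine (`runClassic`) reports classic steps and real time
only; a modified-step count is a notion of the modified process and is
`NA` there.

## Exact solvers

**Monotone dynamic program** (`colonizationExact`). At $r \to \infty$ the
chain over mutant sets is monotone, hence acyclic, and expected times
satisfy a one-pass recursion: with gain rates
$q_w(M) = \sum_{u \in M,\, w \in N(u)} 1/\deg(u)$ and $Q = \sum_w q_w$,

$$E[M] = \frac{n + \sum_w q_w\, E[M \cup \{w\}]}{Q},$$

with classic steps obtained by replacing the $n$ in the numerator by
$|M|$, and real time equal to $E[M]/n$. States are memoized as bitmasks
(so $n \le 64$), and the solver refuses, naming the count reached, beyond
`stateCap` (default $2 \times 10^6$) rather than thrashing.

**Arithmetic.** Exact rational arithmetic (GMP `mpq`) is the default for
$n \le 12$ and available everywhere: expected times on graphs with
heterogeneous degrees have denominators of hundreds of digits already at
$n = 10$, so fixed-width integers are not an option. Float mode (plain
IEEE doubles; each per-state sum has at most $n$ terms) is the default
above $n = 12$, where the state count, not the arithmetic, is the binding
constraint.

**Brute-force oracle** (`colonizationExactBruteForce`, $n \le 14$). The
same quantities by flat enumeration of every mutant superset of the
initial set in inclusion order — no memoized recursion, no reachability
pruning. The suite requires bit-exact agreement with the dynamic program
in rational mode (and $10^{-9}$ relative in float mode) across all
families and seeded random digraphs; a handful of fraction strings from an
independent arbitrary-precision implementation are frozen into the tests
as external anchors.

**Symmetry-reduced recursions.** The star (states: center status × mutant
leaf count, $O(n)$), the double star (both center statuses × leaf counts
per side, $O(k^2)$), and the lollipop (path prefix length × cluster mutant
count, $O(n^{1.5})$, valid because the path colonizes strictly left to
right and cluster nodes are exchangeable) are solved far beyond the subset
solvers. Each is validated against the subset DP at small sizes.

**Closed forms** (`closedFormTime`): backward $n^2(n-1)/2$; cycle
$n(n-1)$ (every stage leaves with probability exactly $1/n$); complete
$2(n-1)H(n-1)$; star $n(n-1)H(n-1)$, identical from center and leaf
starts. Harmonic numbers are summed directly, never approximated. The
star and complete forms are re-derived from the stage decomposition and
confirmed against the oracle in the tests rather than taken on faith.

**Finite fitness** (`absorptionExactClassic`, $n \le 12$). For finite $r$
the chain is not monotone, so the solver builds the full $2^n$-state
absorbing chain sparsely and solves the linear systems for unconditional
expected steps, accrued real time and fixation probability. The $2^n$
ceiling is the true cost of the problem; beyond it, simulation is the only
route, and the cap is enforced loudly.

## Stochastic engines

Both engines run in compiled code. Reproducibility contract: one root
seed, a splitmix64-derived substream per replicate (replicate $i$ is
reproducible in isolation; the first $k$ replicates of a longer run equal
a $k$-replicate run), and hand-rolled unbiased bounded sampling on top of
`mt19937_64`, because the standard library's distribution objects are not
portable across implementations.

The colonization engine can compress idle runs (`skipIdle`, default on):
the number of consecutive resident picks in a state with $m$ mutants is
geometric, and drawing it in one shot never skips a mutant pick, so all
three clocks keep their exact distributions. Selecting a mutant whose
chosen neighbour is already a mutant is a *wasted reproduction* — it
consumes a classic step and real time, because the process has no retry.
Selecting an out-degree-0 node (the total order's sink) is a counted
no-op; such sinks must remain selectable. The classic engine enforces a
step budget (`maxSteps`, default $10^9$) and reports running out of it as
an explicit `truncated` outcome; truncated replicates are excluded from
Monte-Carlo means and flagged, never silently absorbed.

## Graph families and the random fixture generator

Constructors cover the structures the theory distinguishes: complete,
cycle, star, double star $D_{2k}$ (two $S_k$ centers joined), total order
(all edges left to right; the rightmost node is a legal sink), backward
(directed path plus all reverse edges — the unique slowest structure,
where the cubic ceiling is met with equality), lollipop, and a 4-regular
torus as the lattice representative of the regular class. Node indexing is
1-based throughout the R interface, as is idiomatic; node 1 is the
leftmost/path-start node. Edge-list files keep 0-based ids as a plain
interchange dialect.

**Lollipop wiring.** The published description fixes a $\approx\sqrt{n}$
directed path feeding a complete cluster but not the attachment. Here the
last path node sends a one-way edge to *every* cluster node and no edges
lead back to the path, which matches the picture of repeatedly invading
the cluster until an attempt sticks; the attachment rule is a constructor
option (`attach = "one"`) so the choice can be revisited.

**Random fixtures** (`randomReachableDigraph`): independent edge sampling
at probability `edgeProb` (0.4 by default in the audits — dense enough
that rejection until all nodes are reachable from node 1 terminates
quickly at the audit sizes, sparse enough to produce heterogeneous
degrees), rejection-resampled with a bounded retry count, deterministic
given the seed. These fixtures emulate arbitrary reachable digraphs for
bound audits; they do not emulate any particular biological geometry, so
passing audits say the *bounds* hold broadly, not that the samples
resemble real landscapes.

## Experiments

`runScaling` prefers exact routes (reduced solvers and validated closed
forms, the subset DP where the state space permits) and falls back to
seeded simulation; every row carries its method, status and seed, and
skipped points are emitted, not dropped. Slopes are least-squares fits on
log-log points over the top half of the grid, suppressing small-$n$
transients.

`runBoundAudit` certifies, for every audited graph and valid start, the
sandwich $n H(n-1) \le T(G, v) \le n^3/2 - n^2/2$, flags equality cases
(the backward graph from its path start, and nothing else), and checks
the undirected sample against $4 n^2 \sqrt{n}$ — reported rather than
fatal, since that ceiling is asymptotic. One caution from the audits: the
quadratic law for regular graphs is a *ceiling*, attained by the cycle;
the two-dimensional torus grows as a ball and scales like $n^{1.5}$, well
below it.

`runLollipopCrossover` scans the classic-step means of the two lollipop
initializations over a fitness grid. The published phenomenon is the
paradox that seeding the cluster — a strict superset of initial mutants —
*increases* the expected number of classic steps once $r$ is large,
because cluster mutants soak up selection events that no longer advance
the front. The crossover $r^*$ is defined here as the sign change of the
difference of means, linearly interpolated between adjacent grid points,
with a percentile bootstrap CI over replicates; the published figure only
exhibits it graphically. The headline scale ($n = 1600$, $r \in [2, 10]$,
$\ge 10^3$ replicates per point) is an hours-long single-CPU run exposed
by the same call; the suite exercises the machinery at $n = 100$, where
the paradox at $r = 10$ is already decisive. The crossover location moves
with $n$ (at $n = 100$ it sits well above the large-$n$ value), so only
the full-scale run reproduces the published $r^* \approx 2.2$.

## Problem sizes in the checks

The suite and the acceptance script stick to sizes where exact references
exist or Monte-Carlo error is controlled: subset solvers at $n \le 10$
(families) and $n = 8$ (50 random digraphs), the backward chain to
$n = 30$ exactly, reduced solvers to $n = 6400$ (lollipop scaling grid),
$10^4$-replicate simulations at $n \in \{8, 16\}$ compared at $3$ standard
errors, and the scaled-down paradox at $n = 100$, $r = 10$. These are the
package's reference conditions, chosen so that every claim is checked
against an exact value or a bound, not against another simulation.

## Known limitations

* Exact solvers are exponential in general — that is intrinsic (the
  monotone DP's state space is the reachable mutant-set lattice), and the
  symmetry-reduced solvers exist precisely for the families with lumpable
  structure.
* The finite-$r$ solver stops at $n = 12$; there is no subexponential
  exact route for general graphs at finite fitness.
* The half-path construction referred to alongside the backward family is
  defined only in supplementary material not reproduced here and is
  deliberately not implemented.
* Weak selection ($r \to 1$), death-Birth updating, and
  fixation-probability theory beyond what the classic engine records are
  out of scope.

## A worked check

```{r example}
# The backward graph attains the cubic ceiling exactly:
colonizationExact(backwardGraph(8))
# and no audited 8-node structure exceeds it:
audit <- runBoundAudit(8, graphsPerN = 10, seed = 7)
audit$summary[["8"]][c("allUpperOk", "allLowerOk", "maxRatioToCubic",
                       "extremalGraph")]
```
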