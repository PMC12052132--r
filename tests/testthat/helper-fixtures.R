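# Shared fixtures for the suite: every graph is built in code at test time.

# All named families at a given size (only those defined there).
familySet <- function(n) {
  fams <- c("complete", "star", "total_order", "backward")
  if (n >= 3) fams <- c(fams, "cycle")
  if (n >= 4) fams <- c(fams, "lollipop")
  if (n %% 2 == 0 && n >= 4) fams <- c(fams, "double_star")
  stats::setNames(lapply(fams, buildFamily, n = n), fams)
}

# z-score of a Monte-Carlo mean against an exact expectation.
zscore <- function(est, measure, exact) {
  (est@means[[measure]] - exact) / est@se[[measure]]
}

# Exact fraction strings computed with an independent arbitrary-precision
# dynamic program (Python fractions), frozen here as oracle values.
frozenOracle <- list(
  total_order6 = list(
    modified = "2407068090781579/61137675175654",
    classic = "2322921373473299/97101013514274"
  ),
  star5_leaf = list(modified = "125/3", classic = "77/3"),
  lollipop9_path = list(
    modified = "91085913/1746206",
    classic = "40990839/1746206"
  )
)
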