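# Independent oracles and shared fixtures for the suite.

# Brute-force neighbor set: all u with mismatchCount(u, v) <= m, by scanning
# every node. Independent of the XOR-mask enumeration used by the package.
bruteNeighbors <- function(v, d, m) {
  all <- 0:(2L^d - 1L)
  sort(all[mismatchCount(all, rep(v, length(all)), d) <= m])
}

# Exhaustive micro-configuration sum for the window survival probability:
# enumerates every combination of per-group occupied-neighbor counts.
enumSurvival <- function(Lrow, ntilde, tL, tU) {
  active <- which(Lrow > 0)
  if (!length(active)) return(as.numeric(tL <= 0 && 0 <= tU))
  grids <- lapply(active, function(l) 0:Lrow[l])
  combos <- expand.grid(grids)
  tot <- rowSums(combos)
  probs <- rep(1, nrow(combos))
  for (i in seq_along(active)) {
    l <- active[i]
    probs <- probs * dbinom(combos[[i]], Lrow[l], ntilde[l])
  }
  sum(probs[tot >= tL & tot <= tU])
}

# cached expensive fixtures (built at most once per test run)
.fx <- new.env(parent = emptyenv())

graph12 <- function() {
  if (is.null(.fx$g12)) .fx$g12 <- baseGraph(12, 2)
  .fx$g12
}

# a moderately long stationary autonomous run on G_12(2), reused by the
# observables tests
autoRun12 <- function() {
  if (is.null(.fx$auto12)) {
    g <- graph12()
    set.seed(2024)
    st <- idealState(g, referencePattern(12),
                     c(rep(0.68, 5), rep(0, 7)))
    .fx$auto12 <- runAutomaton(g, st, dynamicsParams(0.074, 1, 10),
                               nSteps = 3000)
  }
  .fx$auto12
}

# full with-self insertion protocol at the conditions of the occupation
# table (all of hole group S_10 permanently occupied, p = 0.074), reused by
# the acceptance tests
insertRun12 <- function() {
  if (is.null(.fx$insert12))
    .fx$insert12 <- protocolInsertSelf(graph12(), selfGroup = 10,
                                       p = 0.074, nSteps = 20000,
                                       seed = 42)
  .fx$insert12
}
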