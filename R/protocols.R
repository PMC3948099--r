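#' Orient an inferred pattern so the occupied side carries high indices
#'
#' Flipping all S_1 entries of a pattern maps group \code{g} to
#' \code{G + 1 - g} and leaves the architecture unchanged. This helper fixes
#' the orientation convention used in with-self reports: the highly occupied
#' groups carry the high indices, so that a self group sits among the high
#' groups after reorganization.
#'
#' @param pattern a [PatternSpec-class].
#' @param occ 0/1 occupation vector used to measure which side is occupied.
#' @return the pattern, possibly with flipped S_1 entries.
#' @export
orientPattern <- function(pattern, occ) {
  grp <- nodeGroups(pattern)
  G <- max(grp)
  gm <- rowsum(as.numeric(occ), grp)[, 1L] / tabulate(grp, G)
  half <- floor(G / 2)
  if (sum(gm[seq_len(half)]) > sum(gm[(G - half + 1L):G]))
    pattern <- patternSpec(pattern@d, pattern@positions, 1L - pattern@s1)
  pattern
}

## shared post-run analysis: transitions, post-hoc pattern, group stats,
## roles, self-tolerance summary
.analyzeRun <- function(traj, graph, window, theta, settle, avgSteps,
                        holeThreshold = 0.05, occupiedThreshold = 0.1) {
  nSteps <- length(traj@total)
  events <- detectTransitions(traj, window, theta)
  lastTrans <- if (nrow(events)) max(events$time) else 0L
  from <- max(lastTrans + settle, nSteps - avgSteps + 1L, 1L)
  # short runs cannot honor both the settle and the averaging window;
  # keep at least min(avgSteps, nSteps) trailing steps
  from <- min(from, max(1L, nSteps - min(avgSteps, nSteps) + 1L))
  pat <- inferPattern(traj@com[from:nSteps, , drop = FALSE],
                      window = nSteps - from + 1L, theta = theta)
  if (inherits(pat, "noPattern"))
    return(list(events = events, pattern = pat, stats = NULL,
                roles = NULL, selfGroups = integer(0), tolerant = NA,
                averagedSteps = c(from, nSteps)))
  pat <- orientPattern(pat, traj@finalState@occupation)
  stats <- groupStatistics(traj, graph, pat, from = from, to = nSteps)
  dM <- length(pat@positions)
  L <- linkMatrix(graph@d, dM, graph@m)
  roles <- roleLabels(L, pmin(stats$meanOccupation, 1),
                      occupiedThreshold, holeThreshold)
  grp <- nodeGroups(pat)
  selfGroups <- sort(unique(grp[traj@finalState@selfNodes + 1L]))
  tolerant <- length(selfGroups) > 0 &&
    all(vapply(selfGroups, function(g) {
      linked <- which(L[g, ] > 0)
      all(stats$meanOccupation[linked] < holeThreshold |
            (roles[linked] == "core" &
               stats$meanOccupation[linked] < occupiedThreshold))
    }, logical(1L)))
  list(events = events, pattern = pat, stats = stats, roles = roles,
       selfGroups = selfGroups, tolerant = tolerant,
       averagedSteps = c(from, nSteps))
}

#' Protocol: evolve the network from scratch in the presence of self
#'
#' Starts from an empty base graph with the given nodes permanently
#' occupied and lets the architecture evolve. The emergent pattern is
#' inferred post hoc from the late center-of-mass window, group statistics
#' are computed in that grouping, and the summary reports whether the self
#' nodes ended up in groups whose linked groups are only weakly occupied
#' (self-tolerance).
#'
#' @param graph a [BaseGraph-class].
#' @param selfNodes node indices (0-based) permanently occupied from t = 0.
#' @param p influx probability.
#' @param tL,tU window thresholds.
#' @param nSteps number of steps.
#' @param seed optional seed.
#' @param window,theta pattern-identification window (steps) and band
#'   threshold, as in [inferPattern()].
#' @param settle steps discarded after the last detected transition.
#' @param avgSteps length of the averaging window.
#' @param outDir if given, writes the trajectory TSV, the final state JSON,
#'   and the resolved configuration into this directory.
#' @return list with the trajectory, detected transition events, inferred
#'   pattern, per-group statistics, role labels, the groups containing self
#'   nodes, and the logical \code{tolerant}.
#' @export
protocolEvolveWithSelf <- function(graph, selfNodes, p = 0.05, tL = 1,
                                   tU = 10, nSteps = 20000L, seed = NULL,
                                   window = 500L, theta = 0.2,
                                   settle = 1000L, avgSteps = 5000L,
                                   outDir = NULL) {
  params <- dynamicsParams(p, tL, tU)
  state <- setSelfNodes(emptyState(graph), selfNodes)
  traj <- runAutomaton(graph, state, params, nSteps, seed = seed)
  out <- c(list(trajectory = traj),
           .analyzeRun(traj, graph, window, theta, settle, avgSteps))
  if (!is.null(outDir)) .writeArtifacts(out, graph, outDir, match.call(),
                                        seed)
  out
}

#' Protocol: insert self nodes into an established pattern
#'
#' Seeds an idealized 12-group-style pattern, burns it in, then permanently
#' occupies \code{nSelf} nodes (default: all) of group \code{selfGroup} and
#' follows the reorganization. Transition events are detected from the
#' center-of-mass series; the post-reorganization pattern is inferred post
#' hoc and oriented so the occupied groups carry the high indices (the self
#' group of a full-group insertion then sits at index \code{G - 2}, the
#' anchoring used in with-self occupation tables); statistics are averaged
#' from after the last transition (plus \code{settle}) to the end.
#'
#' @inheritParams protocolEvolveWithSelf
#' @param pattern the established [PatternSpec-class] (default
#'   [referencePattern()] on the graph's d).
#' @param initProbs per-group seeding probabilities for [idealState()];
#'   default 0.68 on the singleton/periphery side (groups 1 to
#'   \code{G/2 - 1}), 0 elsewhere.
#' @param burnIn steps run before the insertion to establish the pattern.
#' @param selfGroup group (of \code{pattern}) whose nodes are occupied.
#' @param nSelf how many nodes of that group (default all).
#' @return as [protocolEvolveWithSelf()], plus the insertion bookkeeping
#'   (\code{selfNodes}, \code{burnIn}).
#' @export
protocolInsertSelf <- function(graph, pattern = referencePattern(graph@d),
                               selfGroup = 10L, nSelf = NULL,
                               initProbs = NULL, burnIn = 500L,
                               p = 0.074, tL = 1, tU = 10,
                               nSteps = 20000L, seed = NULL,
                               window = 500L, theta = 0.2,
                               settle = 1000L, avgSteps = 5000L,
                               outDir = NULL) {
  params <- dynamicsParams(p, tL, tU)
  if (!is.null(seed)) set.seed(seed)
  grp <- nodeGroups(pattern)
  G <- max(grp)
  if (is.null(initProbs)) {
    initProbs <- numeric(G)
    initProbs[seq_len(floor(G / 2) - 1L)] <- 0.68
  }
  state <- idealState(graph, pattern, initProbs)
  burn <- runAutomaton(graph, state, params, burnIn, snapshots = FALSE)
  members <- which(grp == selfGroup) - 1L
  selfNodes <- if (is.null(nSelf) || nSelf >= length(members)) members
               else sort(sample(members, nSelf))
  state <- setSelfNodes(burn@finalState, selfNodes)
  traj <- runAutomaton(graph, state, params, nSteps)
  out <- c(list(trajectory = traj, selfNodes = selfNodes, burnIn = burnIn,
                insertedGroup = selfGroup, initialPattern = pattern),
           .analyzeRun(traj, graph, window, theta, settle, avgSteps))
  if (!is.null(outDir)) .writeArtifacts(out, graph, outDir, match.call(),
                                        seed)
  out
}

.writeArtifacts <- function(out, graph, outDir, call, seed) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeTrajectoryTSV(out$trajectory, file.path(outDir, "trajectory.tsv"))
  writeState(out$trajectory@finalState, file.path(outDir, "final_state.json"),
             meta = list(seed = seed))
  if (!is.null(out$stats))
    utils::write.table(cbind(out$stats, role = out$roles),
                       file.path(outDir, "group_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- c(list(call = deparse(call), d = graph@d, m = graph@m,
                seed = seed, tolerant = out$tolerant,
                selfGroups = out$selfGroups))
  jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
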