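#' Dynamics parameters of the automaton
#'
#' @param p influx probability per empty node per step, in \code{[0, 1]}.
#' @param tL,tU lower and upper window thresholds: an occupied node survives
#'   a parallel update only if its occupied-neighbor count lies in
#'   \code{[tL, tU]}.
#' @return validated parameter list.
#' @export
dynamicsParams <- function(p, tL, tU) {
  tL <- as.integer(tL); tU <- as.integer(tU)
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (tL < 0L || tU < tL) stop("need 0 <= tL <= tU")
  list(p = p, tL = tL, tU = tU)
}

#' Empty occupation state
#'
#' @param graph a [BaseGraph-class] (or an integer bitstring length).
#' @return a [NetworkState-class] with all nodes empty.
#' @export
emptyState <- function(graph) {
  d <- if (is(graph, "BaseGraph")) graph@d else as.integer(graph)
  new("NetworkState", d = d, occupation = integer(2L^d),
      selfNodes = integer(0))
}

#' Declare permanently occupied self nodes
#'
#' The given nodes are added to the self set and set occupied. Self nodes
#' model self antigen: they are counted as occupied neighbors of other nodes
#' but receive no influx and are exempt from the window rule. May be applied
#' at time 0 or to an established state mid-protocol.
#'
#' @param state a [NetworkState-class].
#' @param nodes node indices (0-based) to occupy permanently.
#' @return updated [NetworkState-class].
#' @export
setSelfNodes <- function(state, nodes) {
  nodes <- .checkNode(nodes, state@d)
  occ <- state@occupation
  occ[nodes + 1L] <- 1L
  new("NetworkState", d = state@d, occupation = occ,
      selfNodes = sort(unique(c(state@selfNodes, nodes))))
}

#' Influx step
#'
#' Every empty node independently becomes occupied with probability
#' \code{p}, modeling the random influx of new idiotypes from the bone
#' marrow. Random draws are consumed in node-index order so trajectories are
#' reproducible under a fixed seed.
#'
#' @param state a [NetworkState-class].
#' @param params [dynamicsParams()].
#' @return updated state.
#' @export
influxStep <- function(state, params) {
  occ <- state@occupation
  empty <- occ == 0L
  u <- stats::runif(length(occ))
  occ[empty & u < params$p] <- 1L
  new("NetworkState", d = state@d, occupation = occ,
      selfNodes = state@selfNodes)
}

#' Window-rule step
#'
#' Counts the occupied neighbors \code{n(dv)} of every node in the current
#' configuration simultaneously, then empties every occupied non-self node
#' whose count lies outside \code{[tL, tU]}. Self nodes never change but do
#' contribute to the neighbor counts of others.
#'
#' @param state a [NetworkState-class].
#' @param graph the [BaseGraph-class] the state lives on.
#' @param params [dynamicsParams()].
#' @return updated state.
#' @export
windowStep <- function(state, graph, params) {
  occ <- state@occupation
  cnt <- neighborCounts(graph, occ)
  die <- occ == 1L & (cnt < params$tL | cnt > params$tU)
  if (length(state@selfNodes)) die[state@selfNodes + 1L] <- FALSE
  occ[die] <- 0L
  new("NetworkState", d = state@d, occupation = occ,
      selfNodes = state@selfNodes)
}

#' One full update step
#'
#' Influx first, then the parallel window rule; newly influxed nodes are
#' subject to the same step's window rule.
#'
#' @inheritParams windowStep
#' @return updated state.
#' @export
stepState <- function(state, graph, params) {
  windowStep(influxStep(state, params), graph, params)
}

#' Run the automaton and record a trajectory
#'
#' Applies [stepState()] \code{nSteps} times, recording after every window
#' step the total occupation and the center-of-mass vector, and (by default)
#' a bit-packed occupation snapshot from which per-group statistics and life
#' times can be recomputed afterwards for any grouping.
#'
#' @param graph a [BaseGraph-class].
#' @param state initial [NetworkState-class].
#' @param params [dynamicsParams()].
#' @param nSteps number of steps (>= 0).
#' @param snapshots keep bit-packed per-step occupation snapshots
#'   (\code{2^d / 8} bytes per step); required by [groupStatistics()] and
#'   [meanLifetimes()].
#' @param seed optional integer seed (\code{set.seed}) for reproducibility.
#' @return a [Trajectory-class].
#' @examples
#' g <- baseGraph(8, 1)
#' tr <- runAutomaton(g, emptyState(g), dynamicsParams(0.05, 1, 6),
#'                    nSteps = 50, seed = 1)
#' tail(tr@total)
#' @export
runAutomaton <- function(graph, state, params, nSteps,
                         snapshots = TRUE, seed = NULL) {
  stopifnot(nSteps >= 0, state@d == graph@d)
  if (!is.null(seed)) set.seed(seed)
  nSteps <- as.integer(nSteps)
  nN <- 2L^graph@d
  if (snapshots && as.numeric(nN) / 8 * nSteps > 2e8)
    stop("snapshot storage would exceed 200 MB; set snapshots = FALSE")
  occ <- state@occupation
  selfIdx <- state@selfNodes + 1L
  total <- numeric(nSteps)
  com <- matrix(NA_real_, nSteps, graph@d)
  snap <- if (snapshots) matrix(raw(), nN / 8L, nSteps) else
    matrix(raw(), 0L, 0L)
  p <- params$p; tL <- params$tL; tU <- params$tU
  A <- graph@adjacency
  bits <- graph@bits
  for (t in seq_len(nSteps)) {
    u <- stats::runif(nN)
    occ[occ == 0L & u < p] <- 1L
    cnt <- as.vector(A %*% occ)
    die <- occ == 1L & (cnt < tL | cnt > tU)
    if (length(selfIdx)) die[selfIdx] <- FALSE
    occ[die] <- 0L
    nG <- sum(occ)
    total[t] <- nG
    if (nG > 0) com[t, ] <- (2 * as.vector(crossprod(bits, occ)) - nG) / nG
    if (snapshots) snap[, t] <- packBits(as.integer(occ), "raw")
  }
  final <- new("NetworkState", d = graph@d, occupation = as.integer(occ),
               selfNodes = state@selfNodes)
  new("Trajectory", d = graph@d,
      params = c(params, list(nSteps = nSteps)),
      total = total, com = com, snapshots = snap, finalState = final)
}

## unpack snapshot column t of a trajectory into a 0/1 vector
.snapshotAt <- function(traj, t) {
  if (!ncol(traj@snapshots)) stop("trajectory was run without snapshots")
  as.integer(rawToBits(traj@snapshots[, t]))[seq_len(2L^traj@d)]
}
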