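#' @import methods
#' @importFrom Matrix sparseMatrix crossprod t rowSums colSums
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Base graph of the potential idiotype repertoire
#'
#' All \code{2^d} bitstrings of length \code{d} as nodes, with links between
#' pairs of nodes whose bitstrings are complementary allowing for up to
#' \code{m} mismatches. Every node then has exactly
#' \code{kappa = sum(choose(d, 0:m))} neighbors.
#'
#' @slot d bitstring length.
#' @slot m maximal number of mismatches still counted as complementary.
#' @slot kappa neighborhood size, \code{sum(choose(d, 0:m))}.
#' @slot adjacency sparse 0/1 adjacency matrix (\code{2^d x 2^d}).
#' @slot bits integer matrix (\code{2^d x d}); row \code{v+1} holds the bits
#'   of node \code{v}, column \code{i} the bit \code{b_i} (\code{b_1} is the
#'   least significant bit of the node index).
#'
#' @seealso [baseGraph()], [kappaSize()], [neighborsOf()]
#' @export
setClass("BaseGraph",
  representation(d = "integer", m = "integer", kappa = "integer",
                 adjacency = "Matrix", bits = "matrix"),
  validity = function(object) {
    n <- 2L^object@d
    if (object@m < 0L || object@m >= object@d)
      return("m must satisfy 0 <= m < d")
    if (object@kappa != sum(choose(object@d, 0:object@m)))
      return("kappa does not equal sum(choose(d, 0:m))")
    if (!all(dim(object@adjacency) == c(n, n)))
      return("adjacency has wrong dimensions")
    if (!all(dim(object@bits) == c(n, object@d)))
      return("bits matrix has wrong dimensions")
    TRUE
  })

#' Occupation state of the base graph
#'
#' A 0/1 occupation for every node plus the set of permanently occupied self
#' nodes. Self nodes model permanently present self antigen: they count as
#' occupied neighbors of other nodes but are themselves exempt from the
#' window rule.
#'
#' @slot d bitstring length of the underlying base graph.
#' @slot occupation integer 0/1 vector of length \code{2^d}; entry
#'   \code{v+1} is \code{n(v)}.
#' @slot selfNodes sorted integer vector of node indices (0-based) that are
#'   permanently occupied.
#'
#' @seealso [emptyState()], [setSelfNodes()], [runAutomaton()]
#' @export
setClass("NetworkState",
  representation(d = "integer", occupation = "integer",
                 selfNodes = "integer"),
  validity = function(object) {
    if (length(object@occupation) != 2L^object@d)
      return("occupation must have length 2^d")
    if (!all(object@occupation %in% c(0L, 1L)))
      return("occupation entries must be 0 or 1")
    if (length(object@selfNodes) &&
        (min(object@selfNodes) < 0L || max(object@selfNodes) >= 2L^object@d))
      return("self node indices out of range")
    if (!all(object@occupation[object@selfNodes + 1L] == 1L))
      return("self nodes must be occupied")
    TRUE
  })

#' Determinant-bit pattern of a modular architecture
#'
#' A pattern is defined by its determinant bit positions and by the entries
#' that the reference group S_1 carries at those positions. A node belongs to
#' group S_g if its bitstring differs from the S_1 entries in exactly
#' \code{g - 1} determinant positions; the non-determinant bits are free.
#'
#' @slot d bitstring length.
#' @slot positions determinant bit positions (subset of \code{1:d}; position
#'   \code{i} refers to bit \code{b_i}, with \code{b_1} the least significant
#'   bit of the node index).
#' @slot s1 0/1 entries of group S_1 at \code{positions}.
#'
#' @seealso [patternSpec()], [nodeGroups()], [groupSizes()]
#' @export
setClass("PatternSpec",
  representation(d = "integer", positions = "integer", s1 = "integer"),
  validity = function(object) {
    if (anyDuplicated(object@positions))
      return("determinant positions must be distinct")
    if (length(object@positions) < 1L || length(object@positions) > object@d)
      return("need 1 <= d_M <= d determinant positions")
    if (any(object@positions < 1L) || any(object@positions > object@d))
      return("determinant positions must lie in 1..d")
    if (length(object@s1) != length(object@positions))
      return("s1 entries must match determinant positions")
    if (!all(object@s1 %in% c(0L, 1L)))
      return("s1 entries must be 0 or 1")
    TRUE
  })

#' Recorded trajectory of the automaton
#'
#' Per-step records of a [runAutomaton()] call: total occupation, the
#' center-of-mass vector, and (optionally) bit-packed occupation snapshots
#' from which group statistics and life times can be recomputed for any
#' grouping after the fact.
#'
#' @slot d bitstring length.
#' @slot params list with the dynamics parameters \code{p}, \code{tL},
#'   \code{tU} and the step count.
#' @slot total numeric vector, total occupation \code{n(G)} after the window
#'   step of each recorded step.
#' @slot com numeric matrix (steps x d) of center-of-mass components;
#'   rows are \code{NA} where the graph was empty.
#' @slot snapshots raw matrix (\code{2^d / 8} x steps) of bit-packed
#'   occupations, or a 0-column matrix when snapshots were not kept.
#' @slot finalState the [NetworkState-class] after the last step.
#'
#' @seealso [runAutomaton()], [groupStatistics()], [inferPattern()]
#' @export
setClass("Trajectory",
  representation(d = "integer", params = "list", total = "numeric",
                 com = "matrix", snapshots = "matrix",
                 finalState = "NetworkState"))

#' Result of a mean-field fixed-point iteration
#'
#' @slot n converged (or last) vector of group mean occupations.
#' @slot affected occupations of the sub-populations linked to a single self
#'   node (single-node self mode), or \code{NULL}.
#' @slot converged logical; \code{FALSE} if \code{maxIter} was exhausted.
#' @slot iterations number of iterations performed.
#' @slot residual max-norm change at the last iteration.
#' @slot params list of the map parameters (p, tL, tU, self specification).
#' @slot trace iterate history (iterations x groups) when requested, else a
#'   0-row matrix.
#'
#' @seealso [solveFixedPoint()], [mftMap()]
#' @export
setClass("MftResult",
  representation(n = "numeric", affected = "numericOrNULL",
                 converged = "logical", iterations = "integer",
                 residual = "numeric", params = "list", trace = "matrix"))

setMethod("show", "BaseGraph", function(object) {
  cat(sprintf("BaseGraph G_%d(%d): %d nodes, degree kappa = %d\n",
              object@d, object@m, 2L^object@d, object@kappa))
})

setMethod("show", "NetworkState", function(object) {
  cat(sprintf("NetworkState on %d nodes: %d occupied (%d self)\n",
              2L^object@d, sum(object@occupation), length(object@selfNodes)))
})

setMethod("show", "PatternSpec", function(object) {
  cat(sprintf("PatternSpec: d = %d, d_M = %d groups = %d\n",
              object@d, length(object@positions), length(object@positions) + 1L))
  cat(" determinant positions:", object@positions, "\n")
  cat(" S_1 entries:          ", object@s1, "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d steps on 2^%d nodes (p = %g, window [%d, %d])\n",
              length(object@total), object@d, object@params$p,
              object@params$tL, object@params$tU))
  cat(sprintf(" snapshots kept: %s; final occupation n(G) = %d\n",
              if (ncol(object@snapshots)) "yes" else "no",
              sum(object@finalState@occupation)))
})

setMethod("show", "MftResult", function(object) {
  cat(sprintf("MftResult: %s after %d iterations (residual %.3g)\n",
              if (object@converged) "converged" else "NOT converged",
              object@iterations, object@residual))
  cat(" n* =", round(object@n, 4), "\n")
})

#' @describeIn NetworkState-class occupation vector accessor (0/1, indexed
#'   by node \code{v+1}).
#' @param state a [NetworkState-class].
#' @export
occupation <- function(state) state@occupation

#' @describeIn NetworkState-class self node accessor (0-based indices).
#' @export
selfNodes <- function(state) state@selfNodes

#' @describeIn MftResult-class fixed-point accessor.
#' @param fit an [MftResult-class].
#' @export
fixedPoint <- function(fit) fit@n

#' @describeIn Trajectory-class center-of-mass series accessor
#'   (steps x d matrix).
#' @param traj a [Trajectory-class].
#' @export
comSeries <- function(traj) traj@com
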