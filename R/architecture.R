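#' Group sizes of a modular architecture
#'
#' An architecture with \code{dM} determinant bit positions partitions the
#' \code{2^d} nodes into \code{dM + 1} groups of size
#' \code{|S_g| = 2^(d - dM) * choose(dM, g - 1)}; groups \code{S_g} and
#' \code{S_(dM + 2 - g)} have the same size.
#'
#' @param d bitstring length.
#' @param dM number of determinant positions, \code{1 <= dM <= d}.
#' @return integer vector of length \code{dM + 1}.
#' @examples
#' groupSizes(12, 11)       # 2 22 110 330 660 924 924 660 330 110 22 2
#' sum(groupSizes(12, 11))  # 4096
#' @export
groupSizes <- function(d, dM) {
  d <- as.integer(d); dM <- as.integer(dM)
  if (dM < 1L || dM > d) stop("dM must satisfy 1 <= dM <= d")
  as.integer(2^(d - dM) * choose(dM, 0:dM))
}

#' Construct a pattern specification
#'
#' @param d bitstring length.
#' @param positions determinant bit positions (subset of \code{1:d}).
#' @param s1 0/1 entries of the reference group S_1 at \code{positions}.
#' @return a [PatternSpec-class].
#' @export
patternSpec <- function(d, positions, s1) {
  new("PatternSpec", d = as.integer(d), positions = as.integer(positions),
      s1 = as.integer(s1))
}

#' Reference 12-group pattern on G_12(2)
#'
#' A fixed representative of the 12-group architecture used as a fixture:
#' position 2 is the only non-determinant bit and the S_1 entries are 1 at
#' positions 7, 9, 10, 11, 12 and 0 elsewhere. All patterns with
#' \code{dM = 11} are equivalent under bit permutation/flip symmetry; one is
#' fixed here for reproducibility.
#'
#' @param d bitstring length (default 12).
#' @return a [PatternSpec-class] with \code{dM = d - 1}.
#' @export
referencePattern <- function(d = 12L) {
  d <- as.integer(d)
  pos <- setdiff(seq_len(d), 2L)
  ones <- intersect(c(7L, 9L, 10L, 11L, 12L), pos)
  patternSpec(d, pos, as.integer(pos %in% ones))
}

#' Group membership of nodes
#'
#' A node belongs to group \code{1 + k} where \code{k} is the number of
#' determinant positions at which its bits differ from the S_1 entries.
#'
#' @param pattern a [PatternSpec-class].
#' @param v node indices (0-based); default all \code{2^d} nodes.
#' @return integer group indices in \code{1:(dM + 1)}.
#' @examples
#' p <- referencePattern(12)
#' table(nodeGroups(p))  # matches groupSizes(12, 11)
#' @export
nodeGroups <- function(pattern, v = 0:(2L^pattern@d - 1L)) {
  b <- bitsOf(v, pattern@d)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  diffs <- sweep(b[, pattern@positions, drop = FALSE], 2L, pattern@s1, `!=`)
  1L + as.integer(rowSums(diffs))
}

#' Link matrix of a modular architecture
#'
#' Closed-form count \code{L[i, j]} of neighbors a node of group S_i has in
#' group S_j on the base graph G_d(m):
#' \deqn{L_{ij} = \sum_{k=0}^{m} \sum_{r=0}^{k} \binom{i-1}{r}
#'   \binom{d_M-i+1}{j-1-r} \binom{d-d_M}{k+j-1-2r-(d_M-i+1)},}
#' with binomials of out-of-range arguments equal to zero. Every row sums to
#' \code{kappaSize(d, m)} and the matrix is centrosymmetric.
#'
#' @param d bitstring length.
#' @param dM number of determinant positions.
#' @param m maximal number of mismatches.
#' @return integer matrix (\code{(dM+1) x (dM+1)}).
#' @examples
#' L <- linkMatrix(12, 11, 2)
#' L[1, ]           # 0 ... 0 55 22 2
#' rowSums(L)       # all 79
#' @export
linkMatrix <- function(d, dM, m) {
  d <- as.integer(d); dM <- as.integer(dM); m <- as.integer(m)
  if (dM < 1L || dM > d) stop("dM must satisfy 1 <= dM <= d")
  if (m < 0L || m >= d) stop("m must satisfy 0 <= m < d")
  G <- dM + 1L
  L <- matrix(0L, G, G)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    s <- 0
    for (k in 0:m) for (r in 0:k)
      s <- s + choose(i - 1L, r) * choose(dM - i + 1L, j - 1L - r) *
        choose(d - dM, k + j - 1L - 2L * r - (dM - i + 1L))
    L[i, j] <- as.integer(round(s))
  }
  L
}

#' Brute-force link matrix from the explicit base graph
#'
#' Independent cross-check of [linkMatrix()]: classifies every node of a
#' materialized base graph into its group and counts, for one representative
#' node of each group (or for all nodes), its neighbors in every group.
#'
#' @param graph a [BaseGraph-class].
#' @param pattern a [PatternSpec-class] on the same \code{d}.
#' @param checkAll if \code{TRUE}, verify that all nodes of each group give
#'   the identical row (stops otherwise).
#' @return integer matrix equal to
#'   \code{linkMatrix(d, length(pattern@positions), m)}.
#' @export
linkMatrixBruteforce <- function(graph, pattern, checkAll = FALSE) {
  stopifnot(graph@d == pattern@d)
  grp <- nodeGroups(pattern)
  G <- length(pattern@positions) + 1L
  L <- matrix(0L, G, G)
  for (g in seq_len(G)) {
    members <- which(grp == g) - 1L
    reps <- if (checkAll) members else members[1L]
    rows <- vapply(reps, function(v) {
      tabulate(grp[neighborsOf(v, graph@d, graph@m) + 1L], nbins = G)
    }, integer(G))
    rows <- matrix(rows, nrow = G)
    if (checkAll && ncol(rows) > 1L && any(rows != rows[, 1L]))
      stop(sprintf("nodes of group %d disagree on their link row", g))
    L[g, ] <- rows[, 1L]
  }
  L
}

#' Classify groups into core, periphery, singletons, and stable holes
#'
#' Role classification of an occupation profile over groups: core groups are
#' the groups with intra-group links (\code{L[g, g] > 0}); among the
#' remaining groups, a group is a stable hole if its mean occupation is
#' below \code{holeThreshold}, a singleton if it is occupied (above
#' \code{occupiedThreshold}) and all its linked groups are holes, and
#' periphery if it is occupied and linked to core besides holes. Groups with
#' occupation between the two thresholds, or occupied groups linked to other
#' occupied non-core groups, are labeled \code{"unclassified"} rather than
#' silently guessed.
#'
#' @param L link matrix.
#' @param nStar per-group mean occupations in \code{[0, 1]}.
#' @param occupiedThreshold,holeThreshold classification thresholds; the
#'   observed profiles are bimodal (about 0.68 vs below 0.01) so any
#'   threshold pair in between gives the same labels.
#' @return character vector of roles per group.
#' @export
roleLabels <- function(L, nStar, occupiedThreshold = 0.1,
                       holeThreshold = 0.05) {
  stopifnot(nrow(L) == length(nStar), all(nStar >= 0), all(nStar <= 1))
  G <- length(nStar)
  roles <- rep("unclassified", G)
  core <- diag(L) > 0
  roles[core] <- "core"
  hole <- !core & nStar < holeThreshold
  roles[hole] <- "hole"
  for (g in which(!core & nStar > occupiedThreshold)) {
    linked <- which(L[g, ] > 0)
    if (all(hole[linked])) roles[g] <- "singleton"
    else if (all(hole[linked] | core[linked])) roles[g] <- "periphery"
  }
  roles
}

#' Idealized pattern state
#'
#' Fixture generator standing in for a long burn-in: occupies each node of
#' group g independently with a prescribed per-group probability, so the
#' empirical group occupations match the probabilities up to binomial noise.
#'
#' @param graph a [BaseGraph-class].
#' @param pattern a [PatternSpec-class].
#' @param probs per-group occupation probabilities (length \code{dM + 1}).
#' @return a [NetworkState-class] with no self nodes.
#' @export
idealState <- function(graph, pattern, probs) {
  grp <- nodeGroups(pattern)
  stopifnot(length(probs) == max(grp), all(probs >= 0), all(probs <= 1))
  occ <- as.integer(stats::runif(length(grp)) < probs[grp])
  new("NetworkState", d = graph@d, occupation = occ, selfNodes = integer(0))
}
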