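#' Neighborhood size of the base graph
#'
#' Number of bitstrings complementary to a given bitstring of length
#' \code{d} allowing for up to \code{m} mismatches:
#' \code{kappa = sum_{k=0..m} choose(d, k)}.
#'
#' @param d bitstring length.
#' @param m maximal number of mismatches, \code{0 <= m < d}.
#' @return integer neighborhood size.
#' @examples
#' kappaSize(12, 2)  # 79
#' kappaSize(3, 1)   # 4
#' @export
kappaSize <- function(d, m) {
  d <- as.integer(d); m <- as.integer(m)
  if (length(d) != 1L || length(m) != 1L || is.na(d) || is.na(m))
    stop("d and m must be single integers")
  if (d < 1L) stop("d must be positive")
  if (m < 0L || m >= d) stop("m must satisfy 0 <= m < d")
  as.integer(sum(choose(d, 0:m)))
}

.checkNode <- function(v, d) {
  if (any(v < 0) || any(v >= 2^d)) stop("node index out of range [0, 2^d)")
  as.integer(v)
}

#' Bitwise complement of an idiotype
#'
#' The perfectly complementary idiotype: every bit flipped, restricted to
#' \code{d} bits.
#'
#' @param v node index (0-based integer in \code{[0, 2^d)}); vectorized.
#' @param d bitstring length.
#' @return complementary node index (same length as \code{v}).
#' @examples
#' complementOf(strtoi("010", base = 2), 3)  # 5 == 0b101
#' @export
complementOf <- function(v, d) {
  v <- .checkNode(v, d)
  bitwXor(v, 2L^as.integer(d) - 1L)
}

#' Number of mismatches between two idiotypes
#'
#' A mismatch is a bit position where the two bitstrings are equal, i.e. not
#' complementary; hence mismatches = \code{d - } Hamming distance.
#' Two nodes are linked in the base graph iff their mismatch count is at
#' most \code{m}.
#'
#' @param u,v node indices (0-based); vectorized over the longer argument.
#' @param d bitstring length.
#' @return integer mismatch count in \code{[0, d]}.
#' @examples
#' mismatchCount(strtoi("010", 2), strtoi("111", 2), 3)  # 1
#' @export
mismatchCount <- function(u, v, d) {
  u <- .checkNode(u, d); v <- .checkNode(v, d)
  agree <- bitwXor(bitwXor(u, v), 2L^as.integer(d) - 1L)
  .popcount(agree)
}

.popcount <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

## all XOR offsets from the perfect complement: masks with <= m bits set
.flipMasks <- function(d, m) {
  masks <- 0L
  for (k in seq_len(m)) {
    combs <- utils::combn(d, k)
    masks <- c(masks, as.integer(colSums(matrix(2L^(combs - 1L), nrow = k))))
  }
  sort(masks)
}

#' Neighbors of an idiotype in the base graph
#'
#' All nodes complementary to \code{v} allowing for up to \code{m}
#' mismatches, enumerated by flipping up to \code{m} bits of the perfect
#' complement. The result has exactly \code{kappaSize(d, m)} elements.
#'
#' @param v node index (0-based).
#' @param d bitstring length.
#' @param m maximal number of mismatches.
#' @return sorted integer vector of neighbor node indices.
#' @examples
#' neighborsOf(strtoi("010", 2), 3, 1)  # 1 3 5 7 == 001 011 101 111
#' @export
neighborsOf <- function(v, d, m) {
  v <- .checkNode(v, d)
  stopifnot(length(v) == 1L)
  kappaSize(d, m)  # validates d, m
  sort(bitwXor(complementOf(v, d), .flipMasks(as.integer(d), as.integer(m))))
}

#' Bits of node indices
#'
#' @param v node indices (0-based).
#' @param d bitstring length.
#' @return integer matrix (length(v) x d); column \code{i} is bit \code{b_i}
#'   (least significant bit first).
#' @export
bitsOf <- function(v, d) {
  v <- .checkNode(v, d)
  vapply(seq_len(d), function(i) bitwAnd(bitwShiftR(v, i - 1L), 1L),
         integer(length(v)))
}

#' Format node indices as bitstrings
#'
#' Bitstrings print as \code{b_d b_{d-1} ... b_1}, most significant bit
#' first, matching the usual written form of an idiotype.
#'
#' @param v node indices (0-based).
#' @param d bitstring length.
#' @return character vector of 0/1 strings of length \code{d}.
#' @examples
#' idiotypeString(5, 3)  # "101"
#' @export
idiotypeString <- function(v, d) {
  b <- bitsOf(v, d)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  apply(b[, d:1, drop = FALSE], 1L, paste0, collapse = "")
}

#' Parse bitstrings into node indices
#'
#' Inverse of [idiotypeString()].
#'
#' @param s character vector of 0/1 strings (\code{b_d ... b_1}).
#' @return integer node indices (0-based).
#' @export
parseIdiotype <- function(s) {
  if (!all(grepl("^[01]+$", s))) stop("idiotype strings must be 0/1 only")
  strtoi(s, base = 2L)
}

#' Build the base graph G_d(m)
#'
#' Materializes the adjacency of the base graph as a sparse matrix so that
#' the occupied-neighbor counts of all nodes are a single sparse
#' matrix-vector product. Refuses to build graphs beyond ~1e8 edges.
#'
#' @param d bitstring length.
#' @param m maximal number of mismatches.
#' @return a [BaseGraph-class].
#' @examples
#' g <- baseGraph(3, 1)
#' Matrix::rowSums(g@adjacency)  # all 4
#' @export
baseGraph <- function(d, m) {
  d <- as.integer(d); m <- as.integer(m)
  kap <- kappaSize(d, m)
  nN <- 2L^d
  if (as.numeric(nN) * kap > 1e8)
    stop("base graph too large to materialize (> 1e8 edges)")
  masks <- .flipMasks(d, m)
  nodes <- 0:(nN - 1L)
  neigh <- outer(bitwXor(nodes, nN - 1L), masks, bitwXor)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(nN), length(masks)),
                              j = as.vector(neigh) + 1L, x = 1,
                              dims = c(nN, nN))
  bits <- bitsOf(nodes, d)
  new("BaseGraph", d = d, m = m, kappa = kap, adjacency = adj, bits = bits)
}

#' Occupied-neighbor counts
#'
#' \code{n(dv)} for every node: the number of occupied nodes in each node's
#' neighborhood, computed in one sparse matrix-vector product.
#'
#' @param graph a [BaseGraph-class].
#' @param occ 0/1 occupation vector of length \code{2^d} (or a
#'   [NetworkState-class]).
#' @return numeric vector of neighbor counts, indexed by node \code{v+1}.
#' @export
neighborCounts <- function(graph, occ) {
  if (is(occ, "NetworkState")) occ <- occ@occupation
  as.vector(graph@adjacency %*% as.numeric(occ))
}
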