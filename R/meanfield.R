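#' Self specification for the mean-field theory
#'
#' The modular mean-field theory supports an autonomous network
#' (\code{"none"}), a single permanently occupied node in group \code{s}
#' (\code{"single_node"}), and a fully permanently occupied group
#' (\code{"full_group"}). Intermediate self-node counts are handled by the
#' simulation only.
#'
#' @param mode one of \code{"none"}, \code{"single_node"},
#'   \code{"full_group"}.
#' @param group index of the self group (ignored for \code{"none"}).
#' @return self specification list.
#' @export
selfSpec <- function(mode = c("none", "single_node", "full_group"),
                     group = NA_integer_) {
  mode <- match.arg(mode)
  if (mode != "none" && (is.na(group) || group < 1L))
    stop("self group index required for mode ", mode)
  list(mode = mode, group = as.integer(group))
}

#' Mean occupation after the influx
#'
#' \code{nTilde_l = n_l + p (1 - n_l)}; a fully self-occupied group stays at
#' occupation 1.
#'
#' @param n vector of group mean occupations in \code{[0, 1]}.
#' @param p influx probability.
#' @param self a [selfSpec()].
#' @return post-influx occupation vector.
#' @export
postInflux <- function(n, p, self = selfSpec("none")) {
  stopifnot(all(n >= 0), all(n <= 1))
  nt <- n + p * (1 - n)
  if (self$mode == "full_group") nt[self$group] <- 1
  nt
}

## P(window satisfied) for one node with Lrow[l] neighbors of post-influx
## occupation ntilde[l] per group: distribution of the occupied-neighbor
## total as a sequential convolution of per-group binomials, truncated at
## tU + 1 bins (any partial sum above tU can never re-enter the window).
.survival <- function(Lrow, ntilde, tL, tU) {
  if (tU < 0) return(0)
  tL <- max(tL, 0L)
  pmf <- 1
  excess <- 0        # probability mass already above tU
  for (l in seq_along(Lrow)) {
    if (Lrow[l] == 0L) next
    b <- stats::dbinom(0:Lrow[l], Lrow[l], ntilde[l])
    newLen <- min(length(pmf) + Lrow[l], tU + 1L)
    new <- numeric(newLen)
    for (j in seq_along(b)) {
      if (b[j] == 0) next
      idx <- seq_along(pmf) + (j - 1L)
      keep <- idx <= tU + 1L
      if (any(keep))
        new[idx[keep]] <- new[idx[keep]] + pmf[keep] * b[j]
    }
    pmf <- new
  }
  if (length(pmf) <= tL) 0 else sum(pmf[(tL + 1L):length(pmf)])
}

#' Survival probability of a group under the window rule
#'
#' Probability that the post-influx occupied-neighbor total of a node of
#' group \code{g} lies in the window \code{[tL, tU]}, treating the groups as
#' independent so that the per-group occupied-neighbor counts are binomial
#' with \code{L[g, l]} trials and success probability \code{ntilde[l]}.
#' Computed by sequential binomial convolution truncated at \code{tU};
#' algebraically identical to the sum over all micro-configurations.
#'
#' @param g group index.
#' @param ntilde post-influx group occupations ([postInflux()]).
#' @param L link matrix.
#' @param tL,tU window thresholds.
#' @return probability in \code{[0, 1]}.
#' @export
survivalProbability <- function(g, ntilde, L, tL, tU) {
  stopifnot(all(ntilde >= 0), all(ntilde <= 1), all(L[g, ] >= 0))
  .survival(L[g, ], ntilde, as.integer(tL), as.integer(tU))
}

#' One iteration of the modular mean-field map
#'
#' Updates the vector of group mean occupations: influx
#' \code{nTilde = n + p(1 - n)}, then multiplication by the window-rule
#' survival probability, \code{n'_g = nTilde_g * P(tL <= total <= tU)}.
#'
#' With a fully self-occupied group \code{s}, every node of group \code{g}
#' deterministically sees \code{L[g, s]} occupied self neighbors: group
#' \code{s} is excluded from the stochastic product and both window
#' thresholds are decreased by \code{L[g, s]} (survival is 0 when
#' \code{tU - L[g, s] < 0}); \code{n'_s = 1} always.
#'
#' With a single self node in group \code{s}, the \code{L[s, g]} nodes of
#' each group \code{g} that see the self node use \code{L[g, s] - 1} trials
#' for group \code{s} and thresholds decreased by 1, while the remaining
#' nodes use the unmodified map; the group value is the size-weighted blend
#' of the two sub-populations (plus the self node itself in group
#' \code{s}). The affected sub-population occupations travel along as
#' attributes \code{"affected"} and \code{"unaffected"} of the returned
#' vector. With \code{feedback = FALSE} the blend is not fed back: group
#' averages evolve autonomously and the affected occupations are carried as
#' a purely perturbative bookkeeping.
#'
#' @param n group mean occupations; for single-node self, optionally with
#'   attributes \code{"affected"}/\code{"unaffected"} from a previous
#'   iteration.
#' @param L link matrix.
#' @param p influx probability.
#' @param tL,tU window thresholds.
#' @param self a [selfSpec()].
#' @param sizes group sizes (required for single-node self).
#' @param feedback blend the perturbed sub-populations back into the group
#'   averages (single-node self only).
#' @return updated occupation vector (attributes as above for single-node
#'   self).
#' @export
mftMap <- function(n, L, p, tL, tU, self = selfSpec("none"), sizes = NULL,
                   feedback = TRUE) {
  G <- nrow(L)
  tL <- as.integer(tL); tU <- as.integer(tU)
  if (self$mode == "none") {
    nt <- postInflux(n, p)
    np <- vapply(seq_len(G), function(g) nt[g] * .survival(L[g, ], nt, tL, tU),
                 numeric(1L))
    return(np)
  }
  s <- self$group
  if (self$mode == "full_group") {
    n[s] <- 1
    nt <- postInflux(n, p, self)
    np <- vapply(seq_len(G), function(g) {
      if (g == s) return(1)
      row <- L[g, ]; shift <- row[s]; row[s] <- 0L
      (n[g] + p * (1 - n[g])) * .survival(row, nt, tL - shift, tU - shift)
    }, numeric(1L))
    return(np)
  }
  ## single_node
  if (is.null(sizes)) stop("group sizes required for single-node self")
  u <- attr(n, "unaffected"); a <- attr(n, "affected")
  if (is.null(u)) u <- as.numeric(n)
  if (is.null(a)) a <- as.numeric(n)
  nAvg <- .blendSingle(u, a, L, sizes, s, feedback)
  nt <- nAvg + p * (1 - nAvg)
  uNew <- numeric(G); aNew <- numeric(G)
  for (g in seq_len(G)) {
    ug <- u[g] + p * (1 - u[g])
    uNew[g] <- ug * .survival(L[g, ], nt, tL, tU)
    if (L[s, g] > 0L) {           # group g contains nodes seeing the self
      row <- L[g, ]; row[s] <- max(row[s] - 1L, 0L)
      ag <- a[g] + p * (1 - a[g])
      aNew[g] <- ag * .survival(row, nt, tL - 1L, tU - 1L)
    } else aNew[g] <- uNew[g]
  }
  out <- .blendSingle(uNew, aNew, L, sizes, s, feedback)
  attr(out, "unaffected") <- uNew
  attr(out, "affected") <- aNew
  out
}

## group averages for a single self node in group s: L[s, g] affected nodes
## per group, the self node itself at occupation 1
.blendSingle <- function(u, a, L, sizes, s, feedback) {
  if (!feedback) return(u)
  G <- length(u)
  isSelf <- as.numeric(seq_len(G) == s)
  nAff <- L[s, ]
  (isSelf + nAff * a + (sizes - nAff - isSelf) * u) / sizes
}

#' Iterate the mean-field map to a fixed point
#'
#' Plain iteration of [mftMap()] until the max-norm change falls below
#' \code{tol} or \code{maxIter} is reached. Several fixed points may exist;
#' as a rule of thumb, initial values close to simulated stationary averages
#' converge to the fixed point that reproduces the simulation.
#'
#' @inheritParams mftMap
#' @param n0 initial occupation vector.
#' @param tol max-norm convergence tolerance.
#' @param maxIter iteration cap; non-convergence is flagged, never silently
#'   accepted.
#' @param trace keep the iterate history (e.g. to plot the reorganization
#'   time series).
#' @return an [MftResult-class].
#' @examples
#' L <- linkMatrix(12, 11, 2)
#' fp <- solveFixedPoint(c(rep(0.7, 5), rep(0, 7)), L, 0.074, 1, 10)
#' round(fixedPoint(fp), 4)
#' @export
solveFixedPoint <- function(n0, L, p, tL, tU, self = selfSpec("none"),
                            sizes = NULL, tol = 1e-12, maxIter = 1e5,
                            trace = FALSE, feedback = TRUE) {
  stopifnot(tol > 0)
  n <- n0
  hist <- if (trace) matrix(NA_real_, maxIter, nrow(L)) else
    matrix(NA_real_, 0L, 0L)
  res <- Inf; it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    np <- mftMap(n, L, p, tL, tU, self, sizes, feedback)
    res <- max(abs(as.numeric(np) - as.numeric(n)),
               abs(c(attr(np, "affected"), 0) - c(attr(n, "affected"), 0)))
    if (trace) hist[it, ] <- as.numeric(np)
    n <- np
    if (res < tol) break
  }
  conv <- res < tol
  if (!conv)
    warning(sprintf("fixed-point iteration not converged after %d steps", it))
  new("MftResult", n = as.numeric(n), affected = attr(n, "affected"),
      converged = conv, iterations = it, residual = res,
      params = list(p = p, tL = tL, tU = tU, self = self),
      trace = if (trace) hist[seq_len(it), , drop = FALSE] else hist)
}

#' Mean-field occupied-neighbor count per group
#'
#' The expected occupied-neighbor count of a group-g node at the measurement
#' point, \code{sum_l L[g, l] n*_l}, with a fully self-occupied group
#' contributing occupation 1.
#'
#' @param nStar converged group occupations (vector or [MftResult-class]).
#' @param L link matrix.
#' @param self a [selfSpec()].
#' @return numeric vector over groups.
#' @export
neighborField <- function(nStar, L, self = selfSpec("none")) {
  if (is(nStar, "MftResult")) nStar <- nStar@n
  if (self$mode == "full_group") nStar[self$group] <- 1
  as.vector(L %*% nStar)
}

#' Mirror of a group occupation vector
#'
#' The link matrix of the autonomous network is centrosymmetric, so for
#' every fixed point \code{n*} the reversed vector is also a fixed point.
#' The symmetry is broken when self is present.
#'
#' @param n group occupation vector.
#' @return reversed vector.
#' @export
mirrorState <- function(n) rev(n)
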