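#' Center-of-mass vector of an occupation state
#'
#' The occupation-weighted mean of the node position vectors,
#' \code{R_i = sum_v n(v) (2 b_i(v) - 1) / n(G)}, where bits are mapped to
#' plus/minus 1. For a symmetrically occupied base graph R = 0; a symmetry
#' breaking pattern shows up as components fluctuating around nonzero
#' levels, identifying the determinant bit positions. Self nodes are
#' occupied nodes and enter both sums.
#'
#' @param state a [NetworkState-class].
#' @param graph the matching [BaseGraph-class].
#' @return numeric vector of length d, or all-\code{NA} when the graph is
#'   empty (R is undefined then, not zero).
#' @export
centerOfMass <- function(state, graph) {
  stopifnot(state@d == graph@d)
  nG <- sum(state@occupation)
  if (nG == 0) return(rep(NA_real_, graph@d))
  (2 * as.vector(crossprod(graph@bits, state@occupation)) - nG) / nG
}

## banded classification of windowed means: -1 / 0 / +1
.comBands <- function(com, window, theta) {
  nSteps <- nrow(com)
  wins <- split(seq_len(nSteps), ceiling(seq_len(nSteps) / window))
  bands <- t(vapply(wins, function(ix) {
    mu <- colMeans(com[ix, , drop = FALSE], na.rm = TRUE)
    ifelse(is.nan(mu), 0, sign(mu) * (abs(mu) > theta))
  }, numeric(ncol(com))))
  list(bands = unname(bands),
       ends = unname(vapply(wins, max, integer(1L))))
}

#' Infer the determinant-bit pattern from a center-of-mass series
#'
#' Averages the center-of-mass components over a window of steps; a
#' position whose mean magnitude is below \code{theta} is non-determinant,
#' one above \code{+theta} is determinant with S_1 entry 1, below
#' \code{-theta} determinant with entry 0. Positions whose mean lies within
#' two standard errors of \code{theta} are flagged ambiguous.
#'
#' @param traj a [Trajectory-class] (or a steps x d center-of-mass matrix).
#' @param window number of trailing steps to average (default 500), or an
#'   explicit integer vector of step indices.
#' @param theta band threshold in (0, 1); default 0.2, between the observed
#'   fluctuation levels 0 and roughly 0.4.
#' @return a [PatternSpec-class]; attributes \code{"means"} (windowed means)
#'   and \code{"ambiguous"} (flagged positions).
#' @export
inferPattern <- function(traj, window = 500L, theta = 0.2) {
  com <- if (is(traj, "Trajectory")) traj@com else traj
  d <- ncol(com)
  ix <- if (length(window) > 1L) window else
    seq.int(max(1L, nrow(com) - window + 1L), nrow(com))
  mu <- colMeans(com[ix, , drop = FALSE], na.rm = TRUE)
  se <- apply(com[ix, , drop = FALSE], 2L, stats::sd, na.rm = TRUE) /
    sqrt(length(ix))
  det <- which(abs(mu) > theta)
  if (!length(det)) {
    ## degenerate: no determinant positions; encode as dM = 0 equivalent
    pat <- NULL
  } else {
    pat <- patternSpec(d, det, as.integer(mu[det] > 0))
  }
  amb <- which(abs(abs(mu) - theta) < 2 * se)
  if (is.null(pat)) {
    pat <- structure(list(dM = 0L, means = mu), class = "noPattern")
    attr(pat, "ambiguous") <- amb
    return(pat)
  }
  attr(pat, "means") <- mu
  attr(pat, "ambiguous") <- amb
  pat
}

#' Detect architecture reorganizations in a center-of-mass series
#'
#' Splits the series into consecutive windows, classifies every component
#' into bands (below \code{-theta}, around 0, above \code{+theta}), and
#' reports an event whenever any component's band changes between
#' consecutive windows. Band jumps signal changes of the determinant bits,
#' i.e. a reorganization of the architecture.
#'
#' @inheritParams inferPattern
#' @return data frame with columns \code{time} (last step of the window in
#'   which the new band holds), \code{position}, \code{from}, \code{to};
#'   zero rows for a stationary series.
#' @export
detectTransitions <- function(traj, window = 500L, theta = 0.2) {
  com <- if (is(traj, "Trajectory")) traj@com else traj
  cb <- .comBands(com, window, theta)
  events <- data.frame(time = integer(0), position = integer(0),
                       from = numeric(0), to = numeric(0))
  if (nrow(cb$bands) < 2L) return(events)
  for (w in 2:nrow(cb$bands)) {
    chg <- which(cb$bands[w, ] != cb$bands[w - 1L, ])
    if (length(chg))
      events <- rbind(events, data.frame(
        time = cb$ends[w], position = chg,
        from = cb$bands[w - 1L, chg], to = cb$bands[w, chg]))
  }
  events
}

#' Per-group statistics of a trajectory
#'
#' Time- and group-averaged occupation and occupied-neighbor counts,
#' measured after each window step, recomputed from the trajectory's
#' snapshots for an arbitrary grouping (so the grouping may be inferred
#' after the run). Self nodes are included in their group's averages (their
#' occupation is 1); a column excluding them is reported as well since the
#' autonomous mean-field theory has no self contribution.
#'
#' @param traj a [Trajectory-class] run with snapshots.
#' @param graph the matching [BaseGraph-class].
#' @param grouping a [PatternSpec-class] or an integer group index per node.
#' @param from,to step range to average over (defaults: after the first
#'   half, to the end).
#' @return data frame with one row per group: size, number of self members,
#'   mean occupation (all members / non-self members), mean occupied
#'   neighbor count.
#' @export
groupStatistics <- function(traj, graph, grouping,
                            from = floor(length(traj@total) / 2) + 1L,
                            to = length(traj@total)) {
  grp <- if (is(grouping, "PatternSpec")) nodeGroups(grouping) else
    as.integer(grouping)
  stopifnot(from >= 1L, to <= length(traj@total), from <= to)
  G <- max(grp)
  gsz <- tabulate(grp, G)
  selfIdx <- traj@finalState@selfNodes + 1L
  nSelf <- tabulate(grp[selfIdx], G)
  occSum <- numeric(G); fieldSum <- numeric(G); nT <- 0L
  for (t in seq.int(from, to)) {
    occ <- .snapshotAt(traj, t)
    cnt <- neighborCounts(graph, occ)
    occSum <- occSum + rowsum(as.numeric(occ), grp)[, 1L]
    fieldSum <- fieldSum + rowsum(cnt, grp)[, 1L]
    nT <- nT + 1L
  }
  meanOcc <- occSum / nT / gsz
  nonSelfSz <- gsz - nSelf
  meanOccNS <- ifelse(nonSelfSz > 0,
                      (occSum / nT - nSelf) / nonSelfSz, NA_real_)
  data.frame(group = seq_len(G), size = gsz, nSelf = nSelf,
             meanOccupation = meanOcc,
             meanOccupationNonSelf = meanOccNS,
             meanNeighborOccupation = fieldSum / nT / gsz)
}

#' Mean life times per group
#'
#' The mean length of maximal runs of consecutive occupation of a node,
#' averaged over the nodes of each group within a step range. Runs touching
#' the range boundaries are discarded (censored) rather than truncated,
#' which is unbiased for geometric-like run lengths. Self nodes are excluded
#' (their runs are infinite by construction).
#'
#' @inheritParams groupStatistics
#' @return data frame with per-group number of completed runs and mean life
#'   time; \code{NA} for groups with no completed run.
#' @export
meanLifetimes <- function(traj, grouping,
                          from = floor(length(traj@total) / 2) + 1L,
                          to = length(traj@total)) {
  grp <- if (is(grouping, "PatternSpec")) nodeGroups(grouping) else
    as.integer(grouping)
  stopifnot(from >= 1L, to <= length(traj@total), from < to)
  G <- max(grp)
  nN <- 2L^traj@d
  selfIdx <- traj@finalState@selfNodes + 1L
  runLen <- integer(nN)
  censored <- logical(nN)   # run started at (or before) the range boundary
  sums <- numeric(G); counts <- integer(G)
  first <- TRUE
  for (t in seq.int(from, to)) {
    occ <- .snapshotAt(traj, t)
    if (first) {
      runLen[occ == 1L] <- 1L
      censored[occ == 1L] <- TRUE
      first <- FALSE
      next
    }
    starting <- occ == 1L & runLen == 0L
    continuing <- occ == 1L & runLen > 0L
    ending <- occ == 0L & runLen > 0L
    done <- which(ending & !censored)
    if (length(selfIdx)) done <- setdiff(done, selfIdx)
    if (length(done)) {
      agg <- rowsum(as.numeric(runLen[done]), grp[done])
      g <- as.integer(rownames(agg))
      sums[g] <- sums[g] + agg[, 1L]
      counts[g] <- counts[g] + tabulate(grp[done], G)[g]
    }
    runLen[ending] <- 0L
    censored[ending] <- FALSE
    runLen[continuing] <- runLen[continuing] + 1L
    runLen[starting] <- 1L
  }
  ## runs still open at `to` touch the boundary: discarded
  data.frame(group = seq_len(G), completedRuns = counts,
             meanLifetime = ifelse(counts > 0, sums / counts, NA_real_))
}
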