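test_that("center of mass handles symmetric, single-node, empty states", {
  g <- baseGraph(4, 1)
  full <- new("NetworkState", d = 4L, occupation = rep(1L, 16),
              selfNodes = integer(0))
  expect_equal(centerOfMass(full, g), numeric(4))
  top <- emptyState(g); top@occupation[16] <- 1L   # node 1111
  expect_equal(centerOfMass(top, g), rep(1, 4))
  expect_true(all(is.na(centerOfMass(emptyState(g), g))))
})

test_that("center of mass is invariant under non-determinant relabeling", {
  g <- baseGraph(6, 1)
  pat <- patternSpec(6, c(1, 3, 4, 5, 6), c(1L, 0L, 0L, 1L, 1L))
  grp <- nodeGroups(pat)
  occ <- as.integer(grp <= 2)   # fully occupy groups 1 and 2
  st <- new("NetworkState", d = 6L, occupation = occ,
            selfNodes = integer(0))
  # flipping the non-determinant bit (position 2) permutes nodes within
  # groups; a group-symmetric occupation maps onto itself
  perm <- bitwXor(0:63, 2L) + 1L
  stP <- new("NetworkState", d = 6L, occupation = occ[perm],
             selfNodes = integer(0))
  expect_identical(occ, occ[perm])
  expect_equal(centerOfMass(st, g), centerOfMass(stP, g))
})

test_that("the planted pattern is recovered from a stationary series", {
  tr <- autoRun12()
  pat <- inferPattern(tr, window = 1000)
  ref <- referencePattern(12)
  expect_identical(sort(pat@positions), sort(ref@positions))
  expect_identical(pat@s1[order(pat@positions)],
                   ref@s1[order(ref@positions)])
  # steady 12-group levels: five components near +0.4, six near -0.4,
  # one near 0
  mu <- attr(pat, "means")
  expect_identical(sum(mu > 0.2), 5L)
  expect_identical(sum(mu < -0.2), 6L)
  expect_lt(abs(mu[2]), 0.1)
  expect_true(all(abs(abs(mu[ref@positions]) - 0.4) < 0.15))
})

test_that("a structureless series yields no determinant positions", {
  com <- matrix(rnorm(500 * 12, 0, 0.01), 500, 12)
  pat <- inferPattern(com, window = 500)
  expect_s3_class(pat, "noPattern")
  expect_identical(pat$dM, 0L)
})

test_that("transitions are detected exactly where bands change", {
  # scripted series: component 3 jumps from +0.4 to -0.4 at step 1500
  com <- matrix(0, 3000, 12)
  com[, 5] <- 0.4
  com[1:1500, 3] <- 0.4; com[1501:3000, 3] <- -0.4
  ev <- detectTransitions(com, window = 500, theta = 0.2)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$position, 3L)
  expect_identical(ev$time, 2000L)    # first window entirely in the new band
  expect_identical(c(ev$from, ev$to), c(1, -1))
  # a stationary series has no events
  expect_identical(nrow(detectTransitions(com[1:1500, ], window = 500,
                                          theta = 0.2)), 0L)
})

test_that("group statistics average occupation and neighbor fields", {
  tr <- autoRun12()
  g <- graph12()
  ref <- referencePattern(12)
  st <- groupStatistics(tr, g, ref, from = 1001, to = 3000)
  expect_identical(st$size, groupSizes(12, 11))
  expect_identical(st$nSelf, integer(12))
  # stationary autonomous profile: groups 1-5 occupied, 8-12 empty
  expect_true(all(abs(st$meanOccupation[1:5] - 0.68) < 0.06))
  expect_true(all(st$meanOccupation[8:12] < 0.01))
  # simulation agrees with the mean-field fixed point within 5% on the
  # occupied groups
  L <- linkMatrix(12, 11, 2)
  fp <- solveFixedPoint(c(rep(0.7, 5), rep(0, 7)), L, 0.074, 1, 10)
  relErr <- abs(st$meanOccupation[1:5] - fixedPoint(fp)[1:5]) /
    fixedPoint(fp)[1:5]
  expect_true(all(relErr < 0.05))
  # neighbor fields agree with the link-weighted mean-field sums within 5%
  # on the groups with substantial fields (the holes neighboring the
  # occupied groups, and the core); occupied groups see almost no one
  mftField <- neighborField(fp, L)
  expect_true(all(abs(st$meanNeighborOccupation[6:12] - mftField[6:12]) /
                    mftField[6:12] < 0.05))
  expect_true(all(st$meanNeighborOccupation[1:3] < 0.5))
})

test_that("statistics of an empty trajectory are zero except self", {
  g <- baseGraph(5, 1)
  st <- setSelfNodes(emptyState(g), 7L)
  tr <- runAutomaton(g, st, dynamicsParams(0, 1, 6), 20, seed = 1)
  pat <- patternSpec(5, 1:4, c(1L, 1L, 0L, 0L))
  gs <- groupStatistics(tr, g, pat, from = 1, to = 20)
  grp <- nodeGroups(pat)
  expect_equal(sum(gs$meanOccupation * gs$size), 1)  # just the self node
  expect_identical(gs$nSelf[grp[8]], 1L)
})

test_that("life times average completed occupation runs", {
  # hand-built trajectory on d = 3: node 2 occupied exactly steps 10-14
  nSteps <- 30L
  snap <- matrix(raw(), 1L, nSteps)
  for (t in 1:nSteps) {
    occ <- integer(8)
    if (t >= 10 && t <= 14) occ[3] <- 1L            # node v = 2
    if (t >= 5 && t <= 28) occ[6] <- 1L             # run inside the range
    occ[1] <- 1L                                    # always on: censored
    snap[, t] <- packBits(occ, "raw")
  }
  fin <- new("NetworkState", d = 3L, occupation = integer(8),
             selfNodes = integer(0))
  tr <- new("Trajectory", d = 3L,
            params = list(p = 0, tL = 1, tU = 3, nSteps = nSteps),
            total = rep(1, nSteps), com = matrix(0, nSteps, 3),
            snapshots = snap, finalState = fin)
  grp <- c(1L, 2L, 2L, 3L, 3L, 2L, 3L, 4L)   # groups of nodes 0..7
  lt <- meanLifetimes(tr, grp, from = 1, to = 30)
  expect_equal(lt$meanLifetime[2], (5 + 24) / 2)  # nodes 2 and 5
  expect_identical(lt$completedRuns[2], 2L)
  # node 0's run touches both boundaries: censored, group 1 has no run
  expect_true(is.na(lt$meanLifetime[1]))
  expect_true(is.na(lt$meanLifetime[4]))          # empty group
})

test_that("life times are stationary across disjoint late windows", {
  tr <- autoRun12()
  ref <- referencePattern(12)
  lt1 <- meanLifetimes(tr, ref, from = 1001, to = 2000)
  lt2 <- meanLifetimes(tr, ref, from = 2001, to = 3000)
  # occupied groups have plenty of completed runs and agree within ~10%
  for (gi in 3:5) {
    expect_gt(lt1$completedRuns[gi], 100)
    expect_lt(abs(lt1$meanLifetime[gi] - lt2$meanLifetime[gi]) /
                lt1$meanLifetime[gi], 0.2)
  }
})
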