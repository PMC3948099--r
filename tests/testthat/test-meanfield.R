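test_that("influx update follows nTilde = n + p(1 - n)", {
  expect_equal(postInflux(0, 0.074), 0.074)
  expect_equal(postInflux(1, 0.5), 1)
  expect_equal(postInflux(0.685, 0.074), 0.70831)
  # a fully self-occupied group stays at 1
  expect_equal(postInflux(c(0.2, 0), 0.1, selfSpec("full_group", 2))[2], 1)
})

test_that("survival probability equals the micro-configuration sum", {
  L <- rbind(c(2, 1), c(1, 2))
  expect_equal(survivalProbability(1, c(0.5, 0.5), L, 1, 2),
               enumSurvival(c(2, 1), c(0.5, 0.5), 1, 2))
  expect_equal(survivalProbability(1, c(0, 0), L, 1, 2), 0)
  expect_equal(survivalProbability(1, c(1, 1), L, 0, 2), 0)  # count 3 surely
  set.seed(21)
  for (rep in 1:20) {
    G <- sample(2:4, 1)
    Lrow <- sample(0:4, G, replace = TRUE)
    nt <- runif(G)
    tL <- sample(0:3, 1); tU <- tL + sample(0:4, 1)
    Lm <- matrix(rep(Lrow, G), nrow = G, byrow = TRUE)
    expect_equal(survivalProbability(1, nt, Lm, tL, tU),
                 enumSurvival(Lrow, nt, tL, tU), tolerance = 1e-12)
  }
})

test_that("the map preserves [0,1]^G", {
  L <- linkMatrix(8, 5, 2)
  set.seed(31)
  for (rep in 1:25) {
    n <- runif(6)
    p <- runif(1)
    np <- mftMap(n, L, p, 1, 10)
    expect_true(all(np >= 0 & np <= 1))
  }
})

test_that("the autonomous map commutes with the mirror involution", {
  for (spec in list(c(12, 11, 2), c(8, 5, 2))) {
    L <- linkMatrix(spec[1], spec[2], spec[3])
    set.seed(41)
    for (rep in 1:5) {
      n <- runif(nrow(L))
      expect_equal(mftMap(mirrorState(n), L, 0.06, 1, 10),
                   mirrorState(mftMap(n, L, 0.06, 1, 10)), tolerance = 1e-12)
    }
  }
})

test_that("fixed points: absorbing, autonomous, mirrored", {
  L <- linkMatrix(12, 11, 2)
  fp0 <- solveFixedPoint(runif(12), L, 0, 1, 10)
  expect_true(fp0@converged)
  expect_equal(fixedPoint(fp0), numeric(12))
  fp <- solveFixedPoint(c(rep(0.7, 5), rep(0, 7)), L, 0.074, 1, 10)
  expect_true(fp@converged)
  n <- fixedPoint(fp)
  # residual at the returned point is below tolerance by construction
  expect_lt(max(abs(mftMap(n, L, 0.074, 1, 10) - n)), 1e-11)
  # the mirrored vector is a fixed point too (centrosymmetric L)
  nm <- mirrorState(n)
  expect_lt(max(abs(mftMap(nm, L, 0.074, 1, 10) - nm)), 1e-10)
  # occupied side ~0.68, core/holes ~0
  expect_true(all(abs(n[1:5] - 0.68) < 0.02))
  expect_true(all(n[6:12] < 0.01))
})

test_that("non-convergence is flagged, never silent", {
  L <- linkMatrix(12, 11, 2)
  expect_warning(
    fp <- solveFixedPoint(c(rep(0.7, 5), rep(0, 7)), L, 0.074, 1, 10,
                          maxIter = 3),
    "not converged")
  expect_false(fp@converged)
  expect_identical(fp@iterations, 3L)
})

test_that("full-group self equals an explicit deterministic contribution", {
  # shifting the window by L[g, s] and dropping group s from the product is
  # the same as keeping group s at occupation 1 in the unmodified sum
  L <- linkMatrix(12, 11, 2)
  s <- 10L
  nt <- c(runif(9, 0, 0.8), 1, runif(2, 0, 0.8))
  set.seed(51)
  for (g in c(1L, 2L, 5L, 8L)) {
    row <- L[g, ]; shift <- row[s]; rowX <- row; rowX[s] <- 0L
    Lm <- matrix(rep(rowX, each = 2), nrow = 2)
    expect_equal(survivalProbability(1, nt, Lm, 1 - shift, 10 - shift),
                 enumSurvival(row, nt, 1, 10), tolerance = 1e-12)
  }
})

test_that("full-group self reproduces the with-self occupation profile", {
  L <- linkMatrix(12, 11, 2)
  auto <- solveFixedPoint(c(rep(0.7, 5), rep(0, 7)), L, 0.074, 1, 10)
  ws <- solveFixedPoint(fixedPoint(auto), L, 0.074, 1, 10,
                        selfSpec("full_group", 10))
  n <- fixedPoint(ws)
  expect_equal(n[10], 1)
  # mirrored occupation profile: previous singletons/periphery drop to ~0,
  # previous holes rise to singleton/periphery levels
  expect_true(all(n[1:5] < 1e-6))
  expect_true(all(n[c(8, 9, 11, 12)] > 0.6))
  # the mirror of a with-self fixed point is NOT a fixed point
  nm <- mirrorState(n)
  res <- max(abs(mftMap(nm, L, 0.074, 1, 10,
                        selfSpec("full_group", 10)) - nm))
  expect_gt(res, 0.1)
})

test_that("single-node self depresses the occupations of linked nodes", {
  L <- linkMatrix(12, 11, 2)
  sizes <- groupSizes(12, 11)
  auto <- solveFixedPoint(c(rep(0.7, 5), rep(0, 7)), L, 0.07, 1, 10)
  fp <- solveFixedPoint(fixedPoint(auto), L, 0.07, 1, 10,
                        selfSpec("single_node", 10), sizes = sizes)
  expect_true(fp@converged)
  aff <- fp@affected
  # singleton groups 1-3 are linked to the self's hole group: their nodes
  # that see the self lose roughly 20% occupation
  autoN <- fixedPoint(auto)
  drop <- 1 - aff[1:3] / autoN[1:3]
  expect_true(all(drop > 0.1 & drop < 0.4))
  # the perturbative variant iterates the autonomous group averages
  fpP <- solveFixedPoint(fixedPoint(auto), L, 0.07, 1, 10,
                         selfSpec("single_node", 10), sizes = sizes,
                         feedback = FALSE)
  expect_equal(fixedPoint(fpP), fixedPoint(solveFixedPoint(
    fixedPoint(auto), L, 0.07, 1, 10)), tolerance = 1e-8)
})

test_that("neighbor fields are link-weighted occupation sums", {
  L <- linkMatrix(12, 11, 2)
  expect_equal(neighborField(numeric(12), L), numeric(12))
  n <- c(rep(0, 7), 0.6708, 0.6827, 1, 0.6835, 0.6835)
  f <- neighborField(n, L, selfSpec("full_group", 10))
  expect_equal(f[1], 55 * 1 + 24 * 0.6835)
  expect_equal(f[2], 45 * 0.6827 + 20 + 14 * 0.6835)
})

test_that("mirroring is an involution", {
  x <- runif(7)
  expect_identical(mirrorState(mirrorState(x)), x)
})
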