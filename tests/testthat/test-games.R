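test_that("curvature/drift scalars follow their defining formulas", {
  expect_equal(deriveUC(coordPayoff()), c(u = 2, c = -1))
  expect_equal(deriveUC(matrix(0, 2, 2)), c(u = 0, c = 0))
  expect_equal(deriveUC(matrix(c(3, 5, 0, 1), 2, 2)), c(u = -1, c = -1))
  expect_error(deriveUC(matrix(c(1, NA, 0, 0), 2, 2)), "finite")
  expect_error(deriveUC(diag(3)), "2x2")
})

test_that("pairwise payoff is the bilinear expectation over joint outcomes", {
  expect_equal(pairwisePayoff(coordPayoff(), 1, 1), 1)
  expect_equal(pairwisePayoff(coordPayoff(), 0.5, 0.5), 0.5)
  R <- matrix(c(2, -1, 3, 7), 2, 2)
  expect_equal(pairwisePayoff(R, 0, 0), R[2, 2])
  set.seed(11)
  for (k in 1:20) {
    R <- matrix(runif(4, -3, 3), 2, 2)
    pi <- runif(1); pj <- runif(1)
    expect_equal(pairwisePayoff(R, pi, pj), bruteForcePairPayoff(R, pi, pj))
  }
  expect_error(pairwisePayoff(R, 1.2, 0.5), "\\[0, 1\\]")
})

test_that("expected payoff is the neighbour-weighted pairwise payoff", {
  g2 <- coordinationGame()
  expect_equal(expectedPayoff(g2, rep(0.5, 4), 1), 0.5)
  # weight concentrated on one partner at a pure profile picks r11
  W <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3, byrow = TRUE)
  R <- matrix(c(4, 1, 2, 3), 2, 2)
  g <- socialGame(list(R, coordPayoff(), coordPayoff()), W)
  expect_equal(expectedPayoff(g, c(1, 1, 1), 1), R[1, 1])
  gz <- socialGame(rep(list(matrix(0, 2, 2)), 3), W)
  expect_equal(expectedPayoff(gz, runif(3), 2), 0)
  expect_error(expectedPayoff(g, c(1, 1, 1), 5), "out of range")
})

test_that("expected payoff is affine in own policy with the analytic gradient slope", {
  set.seed(21)
  for (k in 1:10) {
    g <- randomGame(4, seed = 400 + k)
    P <- runif(4)
    i <- sample(4, 1)
    uc <- deriveUC(payoffMatrices(g)[[i]])
    slope <- uc[["u"]] * sum(interactionWeights(g)[i, ] * P) + uc[["c"]]
    # V_i(p_i) must be a line in p_i with that slope (note the weighted
    # opponent mix includes e_ii * p_i = 0 since e_ii = 0)
    P1 <- P; P1[i] <- 0
    P2 <- P; P2[i] <- 1
    v0 <- expectedPayoff(g, P1, i)
    v1 <- expectedPayoff(g, P2, i)
    expect_equal(v1 - v0, slope, tolerance = 1e-12)
    Pm <- P; Pm[i] <- 0.37
    expect_equal(expectedPayoff(g, Pm, i), v0 + 0.37 * slope, tolerance = 1e-12)
  }
})

test_that("the linear model reproduces the worked examples", {
  m1 <- linearModel(cyclingGame())
  expect_equal(systemMatrix(m1),
               matrix(c(0, 1, 0, 1,
                        -1, 0, -1, 0,
                        0, 1, 0, 1,
                        -1, 0, -1, 0), 4, 4, byrow = TRUE))
  expect_equal(driftVector(m1), c(-1, 1, -1, 1))
  m2 <- linearModel(coordinationGame())
  UE2 <- systemMatrix(m2)
  expect_equal(UE2, t(UE2))
  expect_equal(diag(UE2), rep(0, 4))
  expect_equal(driftVector(m2), c(-1, -1, -1, -1))
  gz <- socialGame(rep(list(matrix(0, 2, 2)), 4), bipartiteWeights())
  mz <- linearModel(gz)
  expect_equal(systemMatrix(mz), matrix(0, 4, 4))
  expect_equal(driftVector(mz), rep(0, 4))
})

test_that("UE reconstructs entrywise as u_i * e_ij on random games", {
  set.seed(31)
  for (k in 1:10) {
    g <- randomGame(sample(2:7, 1), seed = 500 + k)
    m <- linearModel(g)
    u <- curvatures(g)
    E <- interactionWeights(g)
    expect_equal(systemMatrix(m), diag(u, nrow = length(u)) %*% E)
    expect_equal(unname(systemMatrix(m)), u * E)
    # row i identically zero iff u_i = 0
    zr <- apply(systemMatrix(m), 1, function(r) all(r == 0))
    expect_equal(zr, u == 0)
  }
})

test_that("random games are reproducible and satisfy the graph invariants", {
  g1 <- randomGame(6, seed = 99)
  g2 <- randomGame(6, seed = 99)
  expect_equal(payoffMatrices(g1), payoffMatrices(g2))
  expect_equal(interactionWeights(g1), interactionWeights(g2))
  for (k in 1:10) {
    g <- randomGame(sample(2:9, 1), seed = k)
    W <- interactionWeights(g)
    expect_true(all(abs(rowSums(W) - 1) <= 1e-12))
    expect_true(all(diag(W) == 0))
    expect_true(all(W >= 0 & W <= 1))
  }
  gr <- randomGame(5, seed = 1, topology = "ring")
  W <- interactionWeights(gr)
  expect_true(all(W[cbind(1:5, c(2:5, 1))] == 1))
  expect_equal(sum(W), 5)
  expect_error(randomGame(1, seed = 1), ">= 2")
})

test_that("planted rest points are exact and leave the system matrix unchanged", {
  set.seed(41)
  for (k in 1:5) {
    fpStar <- runif(4, 0.2, 0.8)
    gRaw <- randomGame(4, seed = 600 + k)
    g <- randomGame(4, seed = 600 + k, plantFixedPoint = fpStar)
    expect_equal(systemMatrix(linearModel(g)), systemMatrix(linearModel(gRaw)))
    fp <- interiorFixedPoint(linearModel(g))
    expect_true(fp$exists)
    expect_equal(fp$point, fpStar, tolerance = 1e-10)
  }
})

test_that("game validation rejects malformed inputs", {
  W <- bipartiteWeights()
  expect_error(socialGame(rep(list(coordPayoff()), 3), W), "payoff count")
  Wbad <- W; Wbad[1, 2] <- 0.4
  expect_error(socialGame(rep(list(coordPayoff()), 4), Wbad), "sums to")
  Wdiag <- W; Wdiag[1, 1] <- 0.1
  expect_error(socialGame(rep(list(coordPayoff()), 4), Wdiag), "diagonal")
  # normalize repairs a scaled row instead of rejecting it
  g <- socialGame(rep(list(coordPayoff()), 4), 2 * W, normalize = TRUE)
  expect_equal(interactionWeights(g), W)
})
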