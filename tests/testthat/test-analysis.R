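test_that("interior fixed point solver covers unique, outside, planted and singular cases", {
  # the cycling game's singular-but-consistent system: minimum-norm
  # representative is the mixed profile at one half
  fp1 <- interiorFixedPoint(linearModel(cyclingGame()))
  expect_true(fp1$exists && fp1$interior)
  expect_equal(fp1$point, rep(0.5, 4), tolerance = 1e-12)
  expect_equal(fp1$status, "degenerate")
  expect_equal(fp1$nullDim, 2L)
  # unique solution outside the open cube
  fpOut <- interiorFixedPoint(linearModel(diag(1, 3), C = rep(-2, 3)))
  expect_true(fpOut$exists)
  expect_false(fpOut$interior)
  expect_equal(fpOut$status, "outside")
  expect_equal(fpOut$point, rep(2, 3))
  # planted interior solutions are recovered to high precision
  set.seed(81)
  for (k in 1:5) {
    UE <- matrix(rnorm(16), 4, 4)        # invertible with probability 1
    Pstar <- runif(4, 0.05, 0.95)
    fp <- interiorFixedPoint(linearModel(UE, C = as.numeric(-UE %*% Pstar)))
    expect_equal(fp$point, Pstar, tolerance = 1e-10)
    expect_equal(fp$status, "interior")
  }
  # inconsistent system
  fpNo <- interiorFixedPoint(linearModel(matrix(c(1, 1, 1, 1), 2, 2), C = c(1, -1)))
  expect_false(fpNo$exists)
  expect_equal(fpNo$status, "inconsistent")
})

test_that("eigen classification labels the worked examples and simple spectra", {
  es1 <- eigenClassify(linearModel(cyclingGame()))
  imag <- sort(Im(es1@values))
  expect_equal(imag, c(-2, 0, 0, 2), tolerance = 1e-9)
  expect_true(all(abs(Re(es1@values)) < 1e-9))
  expect_true(all(es1@labels == "neutral"))
  es2 <- eigenClassify(linearModel(coordinationGame()))
  expect_equal(sort(Re(es2@values)), c(-2, 0, 0, 2), tolerance = 1e-9)
  expect_true(all(Im(es2@values) == 0))
  esd <- eigenClassify(linearModel(diag(c(-1, -3)), C = c(0, 0)))
  expect_true(all(esd@labels == "stable"))
  # eigenpair residuals are enforced by construction
  for (k in seq_along(es1@values))
    expect_lt(sqrt(sum(Mod(systemMatrix(linearModel(cyclingGame())) %*% es1@vectors[, k] -
                            es1@values[k] * es1@vectors[, k])^2)), 1e-8)
})

test_that("the non-convergence certificate returns the cycling plane of the worked example", {
  w <- checkNonconvergence(linearModel(cyclingGame()))
  expect_false(is.null(w))
  expect_equal(w$fixedPoint, rep(0.5, 4))
  expect_equal(w$frequency, 2, tolerance = 1e-9)
  # the witness plane equals span{(0,1,0,1), (1,0,1,0)} up to rotation:
  # projecting both spanning vectors onto the basis must preserve their norm
  B <- w$witnessBasis
  for (v in list(c(0, 1, 0, 1) / sqrt(2), c(1, 0, 1, 0) / sqrt(2))) {
    proj <- B %*% (t(B) %*% v)
    expect_lt(max(abs(proj - v)), 1e-9)
  }
  # symmetric system: no witness
  expect_null(checkNonconvergence(linearModel(coordinationGame())))
  # damped rotation (-1 +/- 2i): real part nonzero, no witness
  mrot <- linearModel(matrix(c(-1, -2, 2, -1), 2, 2), C = c(0.5, 0.5))
  expect_null(checkNonconvergence(mrot))
})

test_that("the convergence certificate prefers symmetry and requires both stability conditions", {
  expect_equal(checkConvergence(linearModel(coordinationGame())), "symmetric")
  expect_null(checkConvergence(linearModel(cyclingGame())))
  # strictly stable, non-symmetric, with interior rest point: hurwitz fires
  UEh <- matrix(c(-1, 0, 0.5, -2), 2, 2)
  mh <- linearModel(UEh, C = as.numeric(-UEh %*% c(0.5, 0.5)))
  expect_equal(checkConvergence(mh), "hurwitz")
  # strictly stable but rest point outside the cube: nothing fires
  mo <- linearModel(UEh, C = c(5, 1))
  expect_null(checkConvergence(mo))
  # a stable diagonal system is symmetric, so the cheaper rule wins
  expect_equal(checkConvergence(linearModel(diag(c(-1, -2)), C = c(0.5, 1))), "symmetric")
})

test_that("classification reproduces the two worked verdicts and an indeterminate case", {
  v1 <- classifyGame(cyclingGame())
  expect_equal(v1@verdict, "NONCONVERGENT_SET_EXISTS")
  expect_equal(v1@firedRule, "imaginary-pair")
  expect_equal(v1@fixedPoint, rep(0.5, 4))
  v2 <- classifyGame(coordinationGame())
  expect_equal(v2@verdict, "CONVERGES_ALL")
  expect_equal(v2@firedRule, "symmetric")
  # 2-agent rotation shifted so the rest point leaves the cube
  g <- socialGame(list(matrix(c(0, -2, 1, 0), 2, 2, byrow = TRUE),
                       matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)),
                  matrix(c(0, 1, 1, 0), 2, 2))
  m <- linearModel(g)
  expect_equal(systemMatrix(m), matrix(c(0, 1, -1, 0), 2, 2, byrow = TRUE))
  v3 <- classifyGame(g)
  expect_equal(v3@verdict, "INDETERMINATE")
  expect_equal(v3@evidence$fixedPointStatus, "outside")
})

test_that("ring detection is exact", {
  expect_true(isRing(ringWeights(4)))
  expect_true(isRing(randomGame(6, seed = 2, topology = "ring")))
  expect_false(isRing(bipartiteWeights()))
  W <- ringWeights(5); W[2, ] <- c(0.5, 0, 0.5, 0, 0)
  expect_false(isRing(W))
})

test_that("dominant strategies follow the sign rule", {
  expect_equal(dominantStrategy(coordPayoff()), "none")      # product -1 < 0
  expect_equal(dominantStrategy(matrix(c(2, 0, 2, 0), 2, 2)), "action1")
  expect_equal(dominantStrategy(matrix(c(0, 1, 0, 1), 2, 2)), "action2")
  expect_equal(dominantStrategy(matrix(0, 2, 2)), "degenerate")
  # weak dominance with one strict inequality counts
  expect_equal(dominantStrategy(matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE)), "action1")
})

test_that("the ring parity rule fires exactly per the parity and sign conditions", {
  # N = 4, all coordination payoffs: u = 2 each, product 16 > 0, none dominant
  g4 <- socialGame(rep(list(coordPayoff()), 4), ringWeights(4))
  w4 <- ringNonconvergence(g4)
  expect_true(w4$fires)
  expect_equal(w4$productU, 16)
  expect_equal(w4$fixedPoint, rep(0.5, 4))
  expect_equal(sort(Im(w4$eigenPair)), c(-2, 2), tolerance = 1e-9)
  # N = 4 with negative product: parity condition unmet
  g4n <- socialGame(list(coordPayoff(), antiPayoff(), coordPayoff(), coordPayoff()),
                    ringWeights(4))
  expect_false(ringNonconvergence(g4n)$fires)
  # N = 6 with exactly one anti-coordination agent: product < 0, fires
  g6 <- socialGame(c(rep(list(coordPayoff()), 5), list(antiPayoff())), ringWeights(6))
  w6 <- ringNonconvergence(g6)
  expect_true(w6$fires)
  expect_lt(w6$productU, 0)
  # dominant strategy blocks the rule
  gd <- socialGame(c(rep(list(coordPayoff()), 3), list(matrix(c(2, 0, 2, 0), 2, 2))),
                   ringWeights(4))
  expect_false(ringNonconvergence(gd)$fires)
  # the classifier routes ring games through the rule
  expect_equal(classifyGame(g4)@firedRule, "ring-parity")
  expect_equal(classifyGame(g4)@verdict, "NONCONVERGENT_SET_EXISTS")
})

test_that("ring spectra satisfy lambda^N = prod(u) and the roots-of-16 example", {
  g4 <- socialGame(rep(list(coordPayoff()), 4), ringWeights(4))
  es <- eigenClassify(linearModel(g4))
  expect_equal(sort(Mod(es@values)), rep(2, 4), tolerance = 1e-9)
  byArg <- sort(round(Arg(es@values) / pi * 2))
  expect_equal(byArg, c(-1, 0, 1, 2))    # {-2i, 2, 2i, -2} as 4th roots of 16
  expect_lt(ringEigenResidual(g4), 1e-8 * 17)
  set.seed(91)
  for (k in 1:12) {
    n <- sample(3:8, 1)
    g <- randomGame(n, seed = 1000 + k, topology = "ring")
    pu <- prod(curvatures(g))
    expect_lt(ringEigenResidual(g), 1e-8 * (1 + abs(pu)))
  }
  # all-zero curvature: all eigenvalues zero
  gz <- socialGame(rep(list(matrix(0, 2, 2)), 4), ringWeights(4))
  expect_equal(ringEigenResidual(gz), 0)
})

test_that("certified convergence is confirmed by simulation on symmetric systems", {
  # exactly symmetric UE: shared curvature u across agents and a symmetric,
  # row-stochastic weight matrix (the bipartite pattern of the worked games)
  set.seed(101)
  for (k in 1:5) {
    u <- runif(1, -3, 3)
    cdrift <- runif(4, -abs(u), 0)
    pays <- lapply(cdrift, function(cc) payoffFromUC(u, cc))
    g <- socialGame(pays, bipartiteWeights())
    m <- linearModel(g)
    expect_equal(checkConvergence(m), "symmetric")
    en <- integrateEnsemble(m, matrix(runif(4 * 25), 4, 25), horizon = 200, step = 0.01)
    expect_true(all(en$fieldNorm < 1e-6))
  }
})

test_that("non-convergence witnesses generate orbits that neither decay nor blow up", {
  v <- classifyGame(cyclingGame())
  B <- v@witnessBasis
  fp <- v@fixedPoint
  eps <- 0.05
  m <- linearModel(cyclingGame())
  set.seed(111)
  for (k in 1:3) {
    ang <- runif(1, 0, 2 * pi)
    P0 <- fp + eps * as.numeric(B %*% c(cos(ang), sin(ang)))
    tr <- integrateFlow(m, P0, horizon = 10 * pi, step = pi / 400, method = "rk4",
                        recordStride = 20L)
    d <- sqrt(rowSums(sweep(tr@states, 2, fp)^2))
    expect_true(all(d >= eps / 2 & d <= 2 * eps))
  }
})
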