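#' @import methods
NULL

.ROW_SUM_TOL <- 1e-12

#' SocialGame: a population of two-action learners on a weighted network
#'
#' An N-agent game consists of one 2x2 payoff matrix per agent (the agent is
#' always the row player of its own matrix) and an N x N neighbour-selection
#' weight matrix. Entry `weights[i, j]` is the probability that agent `i`
#' chooses agent `j` as its partner in a round; every row sums to 1 and the
#' diagonal is zero (no self-play).
#'
#' @slot payoffs list of N numeric 2x2 matrices, `payoffs[[i]][m, n]` being the
#'   reward agent `i` receives when it plays action `m` and its partner plays
#'   action `n`.
#' @slot weights numeric N x N row-stochastic matrix with zero diagonal.
#'
#' @seealso [socialGame()], [randomGame()], [gameFixture()], [linearModel()]
#' @export
setClass("SocialGame", representation(payoffs = "list", weights = "matrix"))

setValidity("SocialGame", function(object) {
  W <- object@weights
  n <- length(object@payoffs)
  if (n < 2L) return("a social game needs at least 2 agents")
  if (!is.numeric(W) || nrow(W) != ncol(W)) return("weights must be a square numeric matrix")
  if (nrow(W) != n) return(sprintf("payoff count (%d) != weight matrix dimension (%d)", n, nrow(W)))
  for (i in seq_len(n)) {
    R <- object@payoffs[[i]]
    if (!is.numeric(R) || !identical(dim(R), c(2L, 2L)))
      return(sprintf("payoff matrix of agent %d is not a numeric 2x2 matrix", i))
    if (!all(is.finite(R)))
      return(sprintf("payoff matrix of agent %d has non-finite entries", i))
  }
  if (!all(is.finite(W))) return("weight matrix has non-finite entries")
  if (any(W < -.ROW_SUM_TOL) || any(W > 1 + .ROW_SUM_TOL))
    return("weight entries must lie in [0, 1]")
  if (any(diag(W) != 0)) return("weight matrix diagonal must be exactly 0 (no self-play)")
  bad <- which(abs(rowSums(W) - 1) > .ROW_SUM_TOL)
  if (length(bad))
    return(sprintf("weight row %d sums to %.15g, not 1 (use normalize = TRUE to rescale)",
                   bad[1L], rowSums(W)[bad[1L]]))
  TRUE
})

#' LinearModel: the linear drift of the expected learning dynamics
#'
#' The expected (infinitesimal-step) learning dynamics of a [SocialGame] are
#' `dP/dt = UE %*% P + C` on the strategy cube, where `U = diag(u_1..u_N)`
#' with `u_i = r11 + r22 - r12 - r21`, `E` is the interaction weight matrix,
#' and `C_i = r12 - r22`. A LinearModel can also be assembled directly from an
#' arbitrary square matrix `UE` and drift vector `C` for analysis of systems
#' that do not arise from a game (in that case the `U`/`E` slots are empty).
#'
#' @slot UE numeric N x N system matrix.
#' @slot C numeric length-N drift vector.
#' @slot U numeric diagonal matrix of the `u_i` (0x0 when constructed raw).
#' @slot E numeric weight matrix (0x0 when constructed raw).
#'
#' @seealso [linearModel()], [interiorFixedPoint()], [eigenClassify()]
#' @export
setClass("LinearModel",
         representation(UE = "matrix", drift = "numeric", U = "matrix", E = "matrix"))

setValidity("LinearModel", function(object) {
  UE <- object@UE
  if (!is.numeric(UE) || nrow(UE) != ncol(UE)) return("UE must be a square numeric matrix")
  if (!all(is.finite(UE))) return("UE has non-finite entries")
  if (length(object@drift) != nrow(UE)) return("length(C) != nrow(UE)")
  if (!all(is.finite(object@drift))) return("C has non-finite entries")
  if (nrow(object@U) > 0L) {
    u <- diag(object@U)
    if (any(object@U[row(object@U) != col(object@U)] != 0)) return("U must be diagonal")
    recon <- u * object@E
    if (max(abs(UE - recon)) > 1e-12 * max(1, max(abs(UE))))
      return("UE does not equal diag(u) %*% E")
  }
  TRUE
})

#' EigenStructure: labelled spectrum of the system matrix
#'
#' Full eigen decomposition of `UE` with every eigenvalue labelled by the sign
#' of its real part: `"stable"` (Re < 0), `"neutral"` (Re = 0 within a
#' scale-relative tolerance) or `"unstable"` (Re > 0). Neutral eigenvalues with
#' nonzero imaginary part generate periodic rotation in the plane of their
#' eigenvector's real and imaginary parts and are the non-convergence trigger.
#'
#' @slot values complex eigenvalues.
#' @slot vectors complex matrix of eigenvectors (columns, unit norm).
#' @slot labels character vector, one of `"stable"`, `"neutral"`, `"unstable"`.
#' @slot zeroTol numeric, the relative tolerance used for the neutral band.
#'
#' @seealso [eigenClassify()]
#' @export
setClass("EigenStructure",
         representation(values = "complex", vectors = "matrix",
                        labels = "character", zeroTol = "numeric"))

setValidity("EigenStructure", function(object) {
  n <- length(object@values)
  if (length(object@labels) != n) return("one label per eigenvalue required")
  if (!all(object@labels %in% c("stable", "neutral", "unstable")))
    return("labels must be 'stable', 'neutral' or 'unstable'")
  if (ncol(object@vectors) != n) return("one eigenvector column per eigenvalue required")
  TRUE
})

#' ConvergenceVerdict: certified classification of the learning dynamics
#'
#' Output of [classifyGame()]. The verdict is one of `"CONVERGES_ALL"` (every
#' start in the cube converges), `"NONCONVERGENT_SET_EXISTS"` (a set of starts
#' near the interior fixed point cycles forever) or `"INDETERMINATE"` (no
#' sufficient condition applies). `firedRule` names the rule that produced the
#' verdict: `"symmetric"` (symmetric UE), `"hurwitz"` (all eigenvalues with
#' negative real part plus an interior fixed point), `"imaginary-pair"` (pure
#' imaginary eigenvalue pair plus an interior fixed point), `"ring-parity"`
#' (ring-topology parity/sign rule) or `"none"`.
#'
#' @slot verdict character scalar, see above.
#' @slot firedRule character scalar, see above.
#' @slot fixedPoint numeric interior fixed point (length 0 when absent).
#' @slot witnessBasis numeric N x 2 orthonormal basis of the cyclic plane
#'   (0-column when absent).
#' @slot eigen the [EigenStructure] of the model.
#' @slot evidence list of auxiliary numeric evidence (stable directions,
#'   rotation frequency, ring diagnostics, ...).
#'
#' @seealso [classifyGame()], [checkConvergence()], [checkNonconvergence()]
#' @export
setClass("ConvergenceVerdict",
         representation(verdict = "character", firedRule = "character",
                        fixedPoint = "numeric", witnessBasis = "matrix",
                        eigen = "EigenStructure", evidence = "list"))

setValidity("ConvergenceVerdict", function(object) {
  if (!object@verdict %in% c("CONVERGES_ALL", "NONCONVERGENT_SET_EXISTS", "INDETERMINATE"))
    return("unknown verdict")
  if (object@verdict == "NONCONVERGENT_SET_EXISTS") {
    if (!length(object@fixedPoint)) return("non-convergence verdict requires a fixed point")
    if (ncol(object@witnessBasis) != 2L) return("non-convergence verdict requires a 2-plane witness")
    lab <- object@eigen@labels
    im <- Im(object@eigen@values)
    if (!any(lab == "neutral" & im != 0))
      return("non-convergence verdict requires a pure imaginary eigenvalue pair")
  }
  if (object@verdict == "CONVERGES_ALL" &&
      !object@firedRule %in% c("symmetric", "hurwitz"))
    return("convergence verdict must come from the symmetric or hurwitz rule")
  TRUE
})

#' Trajectory: a time-stamped path through the strategy cube
#'
#' @slot times strictly increasing numeric vector starting at 0 (continuous
#'   learning time, dimensionless).
#' @slot states numeric matrix with one row per time point and one column per
#'   agent; every entry lies in `[0, 1]`.
#'
#' @seealso [integrateFlow()]
#' @export
setClass("Trajectory", representation(times = "numeric", states = "matrix"))

setValidity("Trajectory", function(object) {
  tt <- object@times
  if (length(tt) != nrow(object@states)) return("one state row per time point required")
  if (length(tt) && tt[1L] != 0) return("times must start at 0")
  if (length(tt) > 1L && any(diff(tt) <= 0)) return("times must be strictly increasing")
  if (any(object@states < -1e-9) || any(object@states > 1 + 1e-9))
    return("states must lie in the unit cube")
  TRUE
})

#' PHCSim: record of a stochastic policy-hill-climbing simulation
#'
#' @slot rounds integer vector of recorded round indices (1-based).
#' @slot policies numeric matrix of recorded policies, one row per recorded
#'   round, one column per agent.
#' @slot cumPayoff numeric matrix of cumulative payoffs at the recorded rounds.
#' @slot finalPolicies numeric vector, the exact policies after the last
#'   simulated round (always recorded, whatever the stride).
#' @slot converged logical, whether the convergence monitor fired.
#' @slot convergedRound integer, round at which it fired (NA otherwise).
#' @slot seed integer master seed (NA when the session RNG was used).
#' @slot alpha,delta numeric learning rates used.
#'
#' @seealso [simulatePHC()]
#' @export
setClass("PHCSim",
         representation(rounds = "integer", policies = "matrix",
                        cumPayoff = "matrix", finalPolicies = "numeric",
                        converged = "logical", convergedRound = "integer",
                        seed = "integer", alpha = "numeric", delta = "numeric"))

setValidity("PHCSim", function(object) {
  if (nrow(object@policies) != length(object@rounds))
    return("one policy row per recorded round required")
  if (any(object@policies < 0) || any(object@policies > 1))
    return("policies must lie in [0, 1]")
  TRUE
})
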