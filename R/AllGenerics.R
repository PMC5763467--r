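#' Number of agents
#'
#' @param x a [SocialGame] or [LinearModel].
#' @return integer scalar.
#' @export
setGeneric("nAgents", function(x) standardGeneric("nAgents"))

#' Per-agent payoff matrices
#'
#' @param x a [SocialGame].
#' @return list of 2x2 numeric matrices.
#' @export
setGeneric("payoffMatrices", function(x) standardGeneric("payoffMatrices"))

#' Neighbour-selection weight matrix
#'
#' @param x a [SocialGame].
#' @return numeric N x N row-stochastic matrix with zero diagonal.
#' @export
setGeneric("interactionWeights", function(x) standardGeneric("interactionWeights"))

#' Assemble the linear drift model of the expected learning dynamics
#'
#' For a [SocialGame] this derives, for every agent, the curvature
#' `u = r11 + r22 - r12 - r21` and drift `c = r12 - r22` and returns the
#' system `dP/dt = UE %*% P + C` with `UE = diag(u) %*% E`. A matrix method
#' accepts an arbitrary square `UE` (plus drift `C`) so that analysis
#' routines can be exercised on systems that do not arise from a game.
#'
#' @param x a [SocialGame], or a numeric square matrix taken as `UE`.
#' @param C numeric drift vector (matrix method only; defaults to zeros).
#' @return a [LinearModel].
#' @examples
#' m <- linearModel(gameFixture("game1_nonconvergent"))
#' systemMatrix(m)
#' driftVector(m)
#' @export
setGeneric("linearModel", function(x, ...) standardGeneric("linearModel"))

#' System matrix UE of a linear model
#' @param x a [LinearModel].
#' @return numeric N x N matrix.
#' @export
setGeneric("systemMatrix", function(x) standardGeneric("systemMatrix"))

#' Drift vector C of a linear model
#' @param x a [LinearModel].
#' @return numeric length-N vector.
#' @export
setGeneric("driftVector", function(x) standardGeneric("driftVector"))

#' Per-agent curvature scalars u_i
#'
#' `u_i = r11 + r22 - r12 - r21` for each agent; `NULL` for models assembled
#' from a raw matrix.
#' @param x a [SocialGame] or [LinearModel].
#' @return numeric vector or `NULL`.
#' @export
setGeneric("curvatures", function(x) standardGeneric("curvatures"))

#' Is the interaction topology a directed ring?
#'
#' TRUE iff `e[i, j] = 1` exactly when `j = (i mod N) + 1` (each agent
#' interacts deterministically with its right-hand neighbour) and 0 elsewhere.
#'
#' @param x a [SocialGame] or a weight matrix.
#' @return logical scalar.
#' @export
setGeneric("isRing", function(x) standardGeneric("isRing"))
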