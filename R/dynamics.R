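## Least-squares/minimum-norm particular solution of UE %*% P = -C via SVD.
## Returns point, residual of UE p + C, and the null-space dimension.
.particularSolution <- function(UE, C) {
  sv <- svd(UE)
  tol <- max(dim(UE)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  rank <- sum(keep)
  p <- if (rank == 0L) numeric(length(C))
       else sv$v[, keep, drop = FALSE] %*%
            ((crossprod(sv$u[, keep, drop = FALSE], -C)) / sv$d[keep])
  p <- as.numeric(p)
  list(point = p,
       residual = sqrt(sum((UE %*% p + C)^2)),
       nullDim = ncol(UE) - rank)
}

#' Constrained flow field of the hybrid learning dynamics
#'
#' The expected learning dynamics are linear, `G = UE %*% P + C`, inside the
#' strategy cube, but a coordinate pinned at a face is frozen whenever the
#' linear field points outward: component `i` of the constrained field is 0
#' when (`P[i] = 0` and `G[i] <= 0`) or (`P[i] = 1` and `G[i] >= 0`) and
#' equals `G[i]` otherwise. A coordinate on a face with `G[i] = 0` is matched
#' by both the frozen and free branch; both give 0, so it is treated as
#' frozen.
#'
#' @param model a [LinearModel].
#' @param P strategy profile in `[0, 1]^N`.
#' @param frozen integer indices of agents whose strategies are held
#'   constant (their field components are forced to 0).
#' @return numeric length-N field vector.
#' @examples
#' m <- linearModel(gameFixture("game1_nonconvergent"))
#' constrainedField(m, rep(0, 4))   # (0, 1, 0, 1)
#' @export
constrainedField <- function(model, P, frozen = integer(0)) {
  stopifnot(is(model, "LinearModel"))
  n <- nAgents(model)
  if (length(P) != n || any(!is.finite(P))) stop("P must be a finite length-N vector")
  if (any(P < -1e-12) || any(P > 1 + 1e-12)) stop("P must lie in the unit cube")
  G <- as.numeric(model@UE %*% P + model@drift)
  G[(P <= 1e-12 & G <= 0) | (P >= 1 - 1e-12 & G >= 0)] <- 0
  G[frozen] <- 0
  G
}

#' Integrate the hybrid learning dynamics
#'
#' Projected explicit integration of `dP/dt = UE %*% P + C` on `[0, 1]^N`:
#' each step advances with the unconstrained linear field and clips the state
#' to the cube, which realizes the boundary sliding rule in the small-step
#' limit (a clipped coordinate re-enters the interior as soon as the field
#' points inward). `method = "euler"` is the reference scheme; `"rk4"` uses a
#' classical 4th-order step (with the same per-step clipping) and is
#' preferable for long interior integrations such as closed orbits, where the
#' first-order scheme's dissipation error accumulates.
#'
#' @param model a [LinearModel].
#' @param P0 starting profile in `[0, 1]^N`.
#' @param horizon total integration time (> 0).
#' @param step time step (> 0); the number of steps is `round(horizon/step)`.
#' @param method `"euler"` (default) or `"rk4"`.
#' @param recordStride record every `recordStride`-th step (the initial and
#'   final states are always recorded).
#' @param frozen integer indices of agents held constant (their coordinates
#'   never move), used to probe the cascade structure of ring topologies.
#' @return a [Trajectory].
#' @examples
#' m <- linearModel(gameFixture("game1_nonconvergent"))
#' tr <- integrateFlow(m, rep(0.5, 4), horizon = 1, step = 1e-2)
#' tail(tr@states, 1)    # the interior fixed point is an equilibrium
#' @export
integrateFlow <- function(model, P0, horizon, step = 1e-3,
                          method = c("euler", "rk4"), recordStride = 1L,
                          frozen = integer(0)) {
  stopifnot(is(model, "LinearModel"))
  method <- match.arg(method)
  n <- nAgents(model)
  if (length(P0) != n || any(P0 < 0) || any(P0 > 1))
    stop("P0 must lie in [0, 1]^N")
  if (!is.finite(step) || step <= 0) stop("step must be > 0")
  if (!is.finite(horizon) || horizon < step) stop("horizon must be >= step")
  UE <- model@UE; C <- model@drift
  nsteps <- max(1L, as.integer(round(horizon / step)))
  recordStride <- max(1L, as.integer(recordStride))
  keep <- setdiff(seq_len(n), frozen)
  nrec <- nsteps %/% recordStride + 2L
  times <- numeric(nrec); states <- matrix(NA_real_, nrec, n)
  P <- as.numeric(P0)
  times[1L] <- 0; states[1L, ] <- P
  k <- 1L
  f <- function(P) as.numeric(UE %*% P + C)
  for (s in seq_len(nsteps)) {
    if (method == "euler") {
      dP <- step * f(P)
    } else {
      k1 <- f(P); k2 <- f(P + step / 2 * k1)
      k3 <- f(P + step / 2 * k2); k4 <- f(P + step * k3)
      dP <- step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    P[keep] <- pmin(1, pmax(0, P[keep] + dP[keep]))
    if (s %% recordStride == 0L || s == nsteps) {
      k <- k + 1L
      times[k] <- s * step; states[k, ] <- P
    }
  }
  new("Trajectory", times = times[seq_len(k)], states = states[seq_len(k), , drop = FALSE])
}

#' Integrate an ensemble of starts to their endpoints
#'
#' Batched projected Euler over many starting profiles at once (one matrix
#' multiply per step), returning only the endpoint of each trajectory and the
#' sup-norm of the constrained field there. Used for convergence surveys
#' where full trajectories are not needed.
#'
#' @param model a [LinearModel].
#' @param starts numeric N x M matrix, one starting profile per column.
#' @param horizon,step as in [integrateFlow()].
#' @return list with `states` (N x M endpoint matrix) and `fieldNorm`
#'   (length-M sup-norm of the constrained field at each endpoint).
#' @export
integrateEnsemble <- function(model, starts, horizon, step = 1e-2) {
  stopifnot(is(model, "LinearModel"))
  P <- as.matrix(starts)
  if (nrow(P) != nAgents(model)) stop("starts must have one row per agent")
  if (any(P < 0) || any(P > 1)) stop("starts must lie in [0, 1]^N")
  UE <- model@UE; C <- model@drift
  nsteps <- max(1L, as.integer(round(horizon / step)))
  for (s in seq_len(nsteps)) {
    P <- P + step * (UE %*% P + C)
    P[P < 0] <- 0; P[P > 1] <- 1
  }
  fn <- apply(P, 2L, function(p) max(abs(constrainedField(model, p))))
  list(states = P, fieldNorm = fn)
}

#' Closed-form solution of the unconstrained linear dynamics
#'
#' The unconstrained flow `dP/dt = UE %*% P + C` has the exact solution
#' `P(t) = expm(t * UE) %*% (P0 - P*) + P*` around any rest point `P*` with
#' `UE %*% P* + C = 0` (the minimum-norm rest point is used; it need not be
#' interior). Computed with a dense matrix exponential and *not* clipped to
#' the cube — this is the analytic oracle against which the projected
#' integrator is validated on interior segments, and it may leave
#' `[0, 1]^N`.
#'
#' @param model a [LinearModel].
#' @param P0 starting profile.
#' @param t numeric time point or vector of time points (>= 0).
#' @return for scalar `t` a length-N vector; for vector `t` a matrix with one
#'   row per time point.
#' @examples
#' m <- linearModel(matrix(c(-1, 0, 0, -1), 2), C = c(0, 0))
#' unconstrainedSolution(m, c(0.5, 0.2), t = 1)   # exp(-1) * P0
#' @export
unconstrainedSolution <- function(model, P0, t) {
  stopifnot(is(model, "LinearModel"))
  n <- nAgents(model)
  if (length(P0) != n) stop("P0 must have one entry per agent")
  ps <- .particularSolution(model@UE, model@drift)
  if (ps$residual > 1e-8 * (1 + sqrt(sum(model@drift^2))))
    stop("no fixed point of the linear flow: the drift C is outside the column space of UE")
  fp <- ps$point
  X0 <- as.numeric(P0) - fp
  out <- t(vapply(t, function(tt) {
    as.numeric(Matrix::expm(tt * model@UE) %*% X0) + fp
  }, numeric(n)))
  if (length(t) == 1L) drop(out) else out
}
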