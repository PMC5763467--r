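#' Construct a social game
#'
#' @param payoffs list of N numeric 2x2 payoff matrices (agent = row player).
#' @param weights numeric N x N neighbour-selection matrix; rows must sum to 1
#'   and the diagonal must be 0 unless `normalize = TRUE`.
#' @param normalize logical; rescale rows of `weights` to sum to 1 (after
#'   zeroing the diagonal) instead of rejecting them. Off by default so that
#'   authoring errors in game files are surfaced, not hidden.
#' @return a [SocialGame].
#' @examples
#' g <- socialGame(rep(list(diag(2)), 3),
#'                 matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0) / 2, 3, 3, byrow = TRUE))
#' nAgents(g)
#' @export
socialGame <- function(payoffs, weights, normalize = FALSE) {
  payoffs <- lapply(payoffs, function(R) {
    R <- as.matrix(R)
    storage.mode(R) <- "double"
    R
  })
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (normalize) {
    diag(weights) <- 0
    rs <- rowSums(weights)
    if (any(rs <= 0)) stop("cannot normalize: a weight row has no positive mass")
    weights <- weights / rs
  }
  new("SocialGame", payoffs = payoffs, weights = weights)
}

#' @rdname nAgents
#' @export
setMethod("nAgents", "SocialGame", function(x) length(x@payoffs))

#' @rdname nAgents
#' @export
setMethod("nAgents", "LinearModel", function(x) nrow(x@UE))

#' @rdname payoffMatrices
#' @export
setMethod("payoffMatrices", "SocialGame", function(x) x@payoffs)

#' @rdname interactionWeights
#' @export
setMethod("interactionWeights", "SocialGame", function(x) x@weights)

#' Curvature and drift scalars of a 2x2 payoff matrix
#'
#' For a payoff matrix `R = [[r11, r12], [r21, r22]]` the expected payoff of
#' the row player against a mixed opponent is affine in its own mixing
#' probability with slope `u * p_opponent + c`, where
#' `u = r11 + r22 - r12 - r21` (interaction curvature) and `c = r12 - r22`
#' (drift). These two scalars fully determine the payoff gradient and hence
#' the learning dynamics.
#'
#' @param R numeric 2x2 payoff matrix with finite entries.
#' @return named numeric vector `c(u = ..., c = ...)`.
#' @examples
#' deriveUC(diag(2))              # u = 2, c = -1
#' deriveUC(matrix(c(3, 5, 0, 1), 2, 2))
#' @export
deriveUC <- function(R) {
  R <- as.matrix(R)
  if (!is.numeric(R) || !all(dim(R) == 2L))
    stop("R must be a numeric 2x2 matrix")
  if (!all(is.finite(R))) stop("payoff entries must be finite")
  c(u = R[1, 1] + R[2, 2] - R[1, 2] - R[2, 1], c = R[1, 2] - R[2, 2])
}

#' Expected payoff of a single 2x2 encounter at a mixed profile
#'
#' Bilinear expectation of the row player's reward when it plays action 1
#' with probability `pi` and the opponent with probability `pj`:
#' `r11*pi*pj + r12*pi*(1-pj) + r21*(1-pi)*pj + r22*(1-pi)*(1-pj)`.
#'
#' @param R numeric 2x2 payoff matrix (row player's rewards).
#' @param pi,pj probabilities of action 1 for the row player and the opponent.
#' @return numeric scalar, expected reward in payoff units.
#' @export
pairwisePayoff <- function(R, pi, pj) {
  R <- as.matrix(R)
  if (!all(is.finite(R)) || !all(dim(R) == 2L)) stop("R must be a finite 2x2 matrix")
  if (!is.finite(pi) || pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
  if (!is.finite(pj) || pj < 0 || pj > 1) stop("pj must lie in [0, 1]")
  R[1, 1] * pi * pj + R[1, 2] * pi * (1 - pj) +
    R[2, 1] * (1 - pi) * pj + R[2, 2] * (1 - pi) * (1 - pj)
}

#' Neighbour-weighted expected payoff of one agent
#'
#' The expected per-round payoff of agent `i` at joint mixed profile `P` is
#' the weighted average, over partners `j` drawn with probability `e[i, j]`,
#' of the pairwise expected payoff of the encounter `(i, j)`.
#'
#' @param game a [SocialGame].
#' @param P numeric strategy profile in `[0, 1]^N`.
#' @param i agent index.
#' @return numeric scalar.
#' @examples
#' g <- gameFixture("game2_convergent")
#' expectedPayoff(g, rep(0.5, 4), 1)   # 0.5
#' @export
expectedPayoff <- function(game, P, i) {
  stopifnot(is(game, "SocialGame"))
  n <- nAgents(game)
  if (length(P) != n || any(!is.finite(P)) || any(P < 0) || any(P > 1))
    stop("P must be a strategy profile in [0, 1]^N")
  if (length(i) != 1L || is.na(i) || i < 1L || i > n) stop("agent index out of range")
  e <- game@weights[i, ]
  R <- game@payoffs[[i]]
  v <- vapply(seq_len(n), function(j) pairwisePayoff(R, P[i], P[j]), numeric(1))
  sum(e * v)
}

#' @rdname linearModel
#' @export
setMethod("linearModel", "SocialGame", function(x, ...) {
  uc <- vapply(x@payoffs, deriveUC, numeric(2))
  u <- uc["u", ]
  U <- diag(u, nrow = length(u))
  new("LinearModel", UE = U %*% x@weights, drift = unname(uc["c", ]),
      U = U, E = x@weights)
})

#' @rdname linearModel
#' @export
setMethod("linearModel", "matrix", function(x, C = numeric(nrow(x)), ...) {
  storage.mode(x) <- "double"
  new("LinearModel", UE = x, drift = as.numeric(C),
      U = matrix(numeric(0), 0, 0), E = matrix(numeric(0), 0, 0))
})

#' @rdname systemMatrix
#' @export
setMethod("systemMatrix", "LinearModel", function(x) x@UE)

#' @rdname driftVector
#' @export
setMethod("driftVector", "LinearModel", function(x) x@drift)

#' @rdname curvatures
#' @export
setMethod("curvatures", "LinearModel",
          function(x) if (nrow(x@U)) diag(x@U) else NULL)

#' @rdname curvatures
#' @export
setMethod("curvatures", "SocialGame",
          function(x) vapply(x@payoffs, function(R) deriveUC(R)[["u"]], numeric(1)))

#' Ring weight matrix
#'
#' @param N number of agents (>= 2).
#' @return N x N matrix with `e[i, (i mod N) + 1] = 1` and 0 elsewhere.
#' @export
ringWeights <- function(N) {
  N <- as.integer(N)
  if (N < 2L) stop("a ring needs at least 2 agents")
  W <- matrix(0, N, N)
  W[cbind(seq_len(N), c(seq_len(N)[-1L], 1L))] <- 1
  W
}

#' @rdname isRing
#' @export
setMethod("isRing", "matrix", function(x) {
  n <- nrow(x)
  if (n < 2L || ncol(x) != n) return(FALSE)
  identical(unname(x == 1), unname(ringWeights(n) == 1)) && all(x %in% c(0, 1))
})

#' @rdname isRing
#' @export
setMethod("isRing", "SocialGame", function(x) isRing(x@weights))

#' Seeded random game generator
#'
#' Draws per-agent payoff entries uniformly on `payoffRange` and builds the
#' interaction network from the requested topology: `"dense"` draws positive
#' weights uniformly, zeroes the diagonal and normalizes rows; `"ring"` uses
#' the deterministic right-neighbour ring; `"custom"` uses the supplied
#' `weights` (validated, not rescaled). The session RNG state is restored on
#' exit, so generation is reproducible and side-effect free.
#'
#' A rest point of the expected dynamics can optionally be planted at a
#' chosen interior profile `P*`: after drawing payoffs and weights, each
#' agent's `r12` entry is shifted so that its drift becomes
#' `c_i = -(UE %*% P*)_i`, which makes `P*` an exact fixed point of
#' `dP/dt = UE %*% P + C` while leaving the curvatures `u_i` (and hence
#' `UE` itself) untouched. This is the reference construction for
#' experiments that need a guaranteed interior rest point.
#'
#' @param N number of agents (>= 2).
#' @param seed integer seed; `NULL` uses (and advances) the session RNG.
#' @param payoffRange numeric length-2 interval for payoff entries.
#' @param topology one of `"dense"`, `"ring"`, `"custom"`.
#' @param weights N x N matrix, required for `topology = "custom"`.
#' @param plantFixedPoint optional interior profile (length N, entries in
#'   (0, 1)) planted as an exact rest point as described above.
#' @return a [SocialGame].
#' @examples
#' g <- randomGame(5, seed = 1, topology = "ring")
#' isRing(g)
#' @export
randomGame <- function(N, seed = NULL, payoffRange = c(-1, 1),
                       topology = c("dense", "ring", "custom"), weights = NULL,
                       plantFixedPoint = NULL) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("N must be an integer >= 2")
  topology <- match.arg(topology)
  stopifnot(length(payoffRange) == 2L, all(is.finite(payoffRange)),
            payoffRange[1] <= payoffRange[2])
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  payoffs <- replicate(N, matrix(stats::runif(4, payoffRange[1], payoffRange[2]), 2, 2),
                       simplify = FALSE)
  W <- switch(topology,
    dense = {
      W <- matrix(stats::runif(N * N), N, N)
      diag(W) <- 0
      W / rowSums(W)
    },
    ring = ringWeights(N),
    custom = {
      if (is.null(weights)) stop("topology = 'custom' requires a weights matrix")
      as.matrix(weights)
    })
  if (!is.null(plantFixedPoint)) {
    fp <- as.numeric(plantFixedPoint)
    if (length(fp) != N || any(fp <= 0) || any(fp >= 1))
      stop("plantFixedPoint must be an interior profile in (0, 1)^N")
    u <- vapply(payoffs, function(R) deriveUC(R)[["u"]], numeric(1))
    cTarget <- as.numeric(-(diag(u, nrow = N) %*% W) %*% fp)
    for (i in seq_len(N)) {
      # c_i = r12 - r22; shifting r12 alone would also change u_i,
      # so r21 is shifted oppositely to keep the curvature fixed
      shift <- cTarget[i] - (payoffs[[i]][1, 2] - payoffs[[i]][2, 2])
      payoffs[[i]][1, 2] <- payoffs[[i]][1, 2] + shift
      payoffs[[i]][2, 1] <- payoffs[[i]][2, 1] - shift
    }
  }
  socialGame(payoffs, W)
}
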