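#' Policy-hill-climbing agent state
#'
#' A stateless (single-state) learner for a repeated two-action game: it keeps
#' one value estimate per action and a policy, the probability of playing
#' action 1. The repeated matrix game has no state transitions, so value
#' learning reduces to exponential averaging of the immediate reward.
#'
#' @param q numeric length-2 action values (payoff units).
#' @param policy probability of action 1.
#' @param alpha value learning rate in (0, 1].
#' @param delta policy learning rate in (0, 1].
#' @return a list of class `"phcAgentState"`.
#' @seealso [phcUpdate()], [simulatePHC()]
#' @export
phcAgentState <- function(q = c(0, 0), policy = 0.5, alpha = 0.1, delta = 0.01) {
  stopifnot(length(q) == 2L, all(is.finite(q)),
            is.finite(policy), policy >= 0, policy <= 1,
            alpha > 0, alpha <= 1, delta > 0, delta <= 1)
  structure(list(q = as.numeric(q), policy = policy, alpha = alpha, delta = delta),
            class = "phcAgentState")
}

#' One policy-hill-climbing update
#'
#' The value of the action just taken is refreshed by exponential averaging,
#' `q[a] <- (1 - alpha) * q[a] + alpha * reward`, and the policy then moves a
#' step `delta` toward the action with the larger value, clipped to `[0, 1]`
#' (the projection onto the valid probability range). An exact value tie
#' leaves the policy unchanged, so ties introduce no drift.
#'
#' @param state a [phcAgentState()].
#' @param action action taken this round, 1 or 2.
#' @param reward numeric reward received.
#' @return the updated state.
#' @examples
#' s <- phcAgentState(q = c(1, 0), policy = 0.5, delta = 0.2)
#' phcUpdate(s, action = 1, reward = 1)$policy   # 0.7
#' @export
phcUpdate <- function(state, action, reward) {
  if (!inherits(state, "phcAgentState")) stop("state must be a phcAgentState")
  if (!action %in% c(1, 2)) stop("action must be 1 or 2")
  if (!is.finite(reward)) stop("reward must be finite")
  state$q[action] <- (1 - state$alpha) * state$q[action] + state$alpha * reward
  d <- state$q[1] - state$q[2]
  if (d != 0)
    state$policy <- min(1, max(0, state$policy + sign(d) * state$delta))
  state
}

## Precompute per-game quantities used every round: cumulative weight rows for
## inverse-CDF neighbour sampling and the payoff tables as an N x 2 x 2 array.
.phcPrep <- function(game) {
  W <- game@weights
  n <- nrow(W)
  Rarr <- array(0, dim = c(n, 2, 2))
  for (i in seq_len(n)) Rarr[i, , ] <- game@payoffs[[i]]
  list(n = n, cumW = t(apply(W, 1L, cumsum)), Rarr = Rarr)
}

## One synchronous round on vectorized state. q: n x 2, p: length n.
## Draw order (fixed, part of the determinism contract): neighbour uniforms,
## own-action uniforms, partner-action uniforms.
.phcStep <- function(prep, q, p, alpha, delta, bothLearn = FALSE) {
  n <- prep$n
  j <- rowSums(stats::runif(n) > prep$cumW) + 1L
  a <- 2L - (stats::runif(n) < p)          # own action: 1 w.p. p[i]
  b <- 2L - (stats::runif(n) < p[j])       # partner's action from its policy
  r <- prep$Rarr[cbind(seq_len(n), a, b)]
  idx <- cbind(seq_len(n), a)
  q[idx] <- (1 - alpha) * q[idx] + alpha * r
  if (bothLearn) {
    # the selected partner also learns, as row player of its own matrix
    for (k in seq_len(n)) {
      jj <- j[k]
      rj <- prep$Rarr[jj, b[k], a[k]]
      q[jj, b[k]] <- (1 - alpha[jj]) * q[jj, b[k]] + alpha[jj] * rj
    }
  }
  d <- q[, 1] - q[, 2]
  p <- pmin(1, pmax(0, p + sign(d) * delta))
  list(q = q, p = p, neighbour = j, action = a, partnerAction = b, reward = r)
}

#' Play one round of the social learning framework
#'
#' Every agent `i` samples a partner `j` with probability `weights[i, j]`,
#' both draw actions from their current policies, and `i` receives the payoff
#' of its own joint action. All agents then update value and policy
#' simultaneously from their own encounter (the sampled partner does not
#' learn from being selected unless `bothLearn = TRUE`).
#'
#' @param game a [SocialGame].
#' @param states list of N [phcAgentState()] objects.
#' @param bothLearn logical; if TRUE the sampled partner also applies an
#'   update from the encounter (as row player of its own payoff matrix).
#' @return list with `states` (updated list) and `record`, a list holding the
#'   sampled `neighbour`, `action`, `partnerAction`, `reward` and the
#'   post-update `policies`.
#' @export
playRound <- function(game, states, bothLearn = FALSE) {
  stopifnot(is(game, "SocialGame"), length(states) == nAgents(game))
  prep <- .phcPrep(game)
  q <- t(vapply(states, function(s) s$q, numeric(2)))
  p <- vapply(states, function(s) s$policy, numeric(1))
  alpha <- vapply(states, function(s) s$alpha, numeric(1))
  delta <- vapply(states, function(s) s$delta, numeric(1))
  st <- .phcStep(prep, q, p, alpha, delta, bothLearn)
  states <- lapply(seq_along(states), function(i) {
    s <- states[[i]]
    s$q <- st$q[i, ]
    s$policy <- st$p[i]
    s
  })
  list(states = states,
       record = list(neighbour = st$neighbour, action = st$action,
                     partnerAction = st$partnerAction, reward = st$reward,
                     policies = st$p))
}

#' Simulate the social learning framework with PHC learners
#'
#' Runs `rounds` synchronous rounds of [playRound()] semantics on a single
#' seeded RNG stream. A convergence monitor watches the maximum absolute
#' policy change per round: once it stays below `monitorTol` for
#' `monitorWindow` consecutive rounds the run is flagged converged and (by
#' default) stopped early. The monitor detects a quiet window; games whose
#' learners cycle can also dwell quietly at a cube corner for long stretches
#' while value estimates drift toward the next preference flip, so for
#' oscillation detection use dispersion statistics over the recorded
#' trajectory instead (see [compareDynamics()]).
#'
#' @param game a [SocialGame].
#' @param rounds number of rounds (>= 1).
#' @param alpha value learning rate in (0, 1] (scalar or length N).
#' @param delta policy learning rate in (0, 1] (scalar or length N).
#' @param seed integer master seed; `NULL` uses the session RNG.
#' @param initialPolicy starting policies (scalar or length N), default 0.5.
#' @param recordStride record every `recordStride`-th round (the final round
#'   is always recorded).
#' @param bothLearn see [playRound()].
#' @param monitorWindow,monitorTol convergence monitor parameters.
#' @param earlyStop logical, stop once the monitor fires.
#' @return a [PHCSim].
#' @examples
#' sim <- simulatePHC(gameFixture("game2_convergent"), rounds = 2000, seed = 1)
#' sim@finalPolicies
#' @export
simulatePHC <- function(game, rounds, alpha = 0.1, delta = 0.01, seed = NULL,
                        initialPolicy = 0.5, recordStride = 1L,
                        bothLearn = FALSE, monitorWindow = 1000L,
                        monitorTol = 1e-4, earlyStop = TRUE) {
  stopifnot(is(game, "SocialGame"))
  rounds <- as.integer(rounds)
  if (is.na(rounds) || rounds < 1L) stop("rounds must be >= 1")
  n <- nAgents(game)
  alpha <- rep_len(alpha, n); delta <- rep_len(delta, n)
  stopifnot(all(alpha > 0), all(alpha <= 1), all(delta > 0), all(delta <= 1))
  p <- rep_len(initialPolicy, n)
  if (any(p < 0) || any(p > 1)) stop("initial policies must lie in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  prep <- .phcPrep(game)
  q <- matrix(0, n, 2)
  cum <- numeric(n)
  recordStride <- max(1L, as.integer(recordStride))
  nrec <- rounds %/% recordStride + 2L
  recRound <- integer(nrec); recP <- matrix(NA_real_, nrec, n)
  recPay <- matrix(NA_real_, nrec, n)
  k <- 0L
  quiet <- 0L; converged <- FALSE; convergedRound <- NA_integer_
  lastRound <- rounds
  for (r in seq_len(rounds)) {
    st <- .phcStep(prep, q, p, alpha, delta, bothLearn)
    q <- st$q
    dmax <- max(abs(st$p - p))
    p <- st$p
    cum <- cum + st$reward
    if (r %% recordStride == 0L) {
      k <- k + 1L
      recRound[k] <- r; recP[k, ] <- p; recPay[k, ] <- cum
    }
    quiet <- if (dmax < monitorTol) quiet + 1L else 0L
    if (!converged && quiet >= monitorWindow) {
      converged <- TRUE
      convergedRound <- r
      if (earlyStop) { lastRound <- r; break }
    }
  }
  if (k == 0L || recRound[k] != lastRound) {
    k <- k + 1L
    recRound[k] <- lastRound; recP[k, ] <- p; recPay[k, ] <- cum
  }
  new("PHCSim",
      rounds = recRound[seq_len(k)], policies = recP[seq_len(k), , drop = FALSE],
      cumPayoff = recPay[seq_len(k), , drop = FALSE], finalPolicies = p,
      converged = converged, convergedRound = convergedRound,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      alpha = alpha, delta = delta)
}
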