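#' Compare the stochastic learners with the differential model
#'
#' Runs the policy-hill-climbing simulation and the projected integration of
#' the differential model from the same (seed-drawn) interior starting
#' profile and reports whether each engine settles. The differential model
#' counts as converged when the sup-norm of the constrained field at the
#' horizon is below `fieldTol`. The stochastic engine counts as converged
#' when every policy's standard deviation over the final fifth of the run is
#' below `sdTol`: dispersion is the robust terminal statistic here, because
#' the per-round quiet monitor of [simulatePHC()] also goes quiet during the
#' corner dwell phases of a limit cycle (policies sit pinned while the value
#' estimates drift toward the next flip) and would misread cycling as
#' convergence.
#'
#' @param game a [SocialGame].
#' @param seed integer master seed (also seeds the shared starting profile).
#' @param rounds simulation rounds.
#' @param horizon,step integration horizon and step.
#' @param alpha,delta learning rates for the simulator.
#' @param fieldTol field sup-norm below which the differential model counts
#'   as converged.
#' @param sdTol per-policy terminal standard deviation below which the
#'   stochastic engine counts as converged.
#' @return list with `p0`, `phc` (list: converged, finalPolicies,
#'   terminalSd, monitorFired), `ode` (list: converged, terminal, fieldNorm),
#'   `agree` (logical, same terminal behaviour) and `terminalDistance`
#'   (numeric, NA unless both converge).
#' @examples
#' \donttest{
#' compareDynamics(gameFixture("game2_convergent"), seed = 1, rounds = 20000)$agree
#' }
#' @export
compareDynamics <- function(game, seed, rounds = 50000, horizon = 200,
                            step = 1e-2, alpha = 0.1, delta = 0.01,
                            fieldTol = 1e-6, sdTol = 0.05) {
  stopifnot(is(game, "SocialGame"))
  n <- nAgents(game)
  set.seed(as.integer(seed))
  p0 <- stats::runif(n, 0.2, 0.8)
  sim <- simulatePHC(game, rounds = rounds, alpha = alpha, delta = delta,
                     seed = seed, initialPolicy = p0, recordStride = 10L,
                     earlyStop = FALSE)
  tail <- sim@rounds > 0.8 * rounds
  terminalSd <- apply(sim@policies[tail, , drop = FALSE], 2L, stats::sd)
  phcConv <- all(terminalSd < sdTol)
  model <- linearModel(game)
  tr <- integrateFlow(model, p0, horizon = horizon, step = step,
                      recordStride = 1000L)
  terminal <- tr@states[nrow(tr@states), ]
  fieldNorm <- max(abs(constrainedField(model, terminal)))
  odeConv <- fieldNorm < fieldTol
  list(p0 = p0,
       phc = list(converged = phcConv, finalPolicies = sim@finalPolicies,
                  terminalSd = terminalSd, monitorFired = sim@converged),
       ode = list(converged = odeConv, terminal = terminal, fieldNorm = fieldNorm),
       agree = identical(phcConv, odeConv),
       terminalDistance = if (phcConv && odeConv)
         sqrt(sum((sim@finalPolicies - terminal)^2)) else NA_real_)
}
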