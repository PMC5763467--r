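# Builders shared across test files.

# Bipartite 4-agent weight matrix of the worked examples.
bipartiteWeights <- function() {
  matrix(c(0, .5, 0, .5,
           .5, 0, .5, 0,
           0, .5, 0, .5,
           .5, 0, .5, 0), 4, 4, byrow = TRUE)
}

coordPayoff <- function() matrix(c(1, 0, 0, 1), 2, 2)      # identity: u = 2, c = -1
antiPayoff  <- function() matrix(c(0, 1, 1, 0), 2, 2)      # u = -2, c = 1

# The two worked games built in code (independent of the packaged JSON).
cyclingGame <- function() {
  socialGame(list(coordPayoff(), antiPayoff(), coordPayoff(), antiPayoff()),
             bipartiteWeights())
}

coordinationGame <- function() {
  socialGame(rep(list(coordPayoff()), 4), bipartiteWeights())
}

# Payoff matrix with prescribed curvature u and drift c (r21 = r22 = 0).
payoffFromUC <- function(u, c) matrix(c(u + c, c, 0, 0), 2, 2, byrow = TRUE)

# Brute-force expected payoff: enumerate the four joint outcomes.
bruteForcePairPayoff <- function(R, pi, pj) {
  probs <- c(pi * pj, pi * (1 - pj), (1 - pi) * pj, (1 - pi) * (1 - pj))
  sum(probs * c(R[1, 1], R[1, 2], R[2, 1], R[2, 2]))
}
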