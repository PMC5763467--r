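---
title: "Social learning dynamics on interaction networks: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Social learning dynamics on interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellswarm)
```

## The model

A population of $N$ agents sits on a weighted directed network. Entry
$e_{ij}$ of the weight matrix $E$ is the probability that agent $i$ selects
agent $j$ as its partner for the current round; every row sums to one and
$e_{ii} = 0$. An encounter is a two-action game: agent $i$ holds a fixed
$2\times 2$ payoff matrix $R_i$ with entries $r_i^{mn}$, its reward when it
plays action $m$ against a partner playing $n$. The payoff depends only on
the joint action, not on which neighbour is faced. Strategies are mixed:
$p_i \in [0,1]$ is the probability of action 1, and the joint state is a
point $P \in [0,1]^N$.

Two scalars per agent carry all the information the learning dynamics need:
the *curvature* $u_i = r_i^{11} + r_i^{22} - r_i^{12} - r_i^{21}$ and the
*drift* $c_i = r_i^{12} - r_i^{22}$. The expected payoff of agent $i$ is the
neighbour-weighted average of the bilinear pairwise expectations, and it is
affine in the agent's own policy with slope
$G_i = u_i \sum_j e_{ij} p_j + c_i$ — the payoff gradient. (The package
treats the weighted sum form as definitive; `expectedPayoff` is tested to be
affine with exactly this slope.)

### The stochastic learner

Each agent is a stateless policy hill-climber: it keeps one value estimate
per action and, after receiving reward $r$ for action $a$, updates
$q_a \leftarrow (1-\alpha) q_a + \alpha r$ and moves its policy a step
$\delta$ toward $\arg\max_a q_a$, clipped to $[0,1]$. Because the repeated
matrix game has no state transitions, value learning with discounting
degenerates to this exponential average; that is the package's reading of
tabular learning in this setting. An exact value tie moves nothing, so ties
introduce no seed-dependent drift.

Update timing is synchronous: every round each agent samples one partner,
both sides draw actions from their current policies, and each agent updates
once, from its own encounter only. The sampled partner does not learn from
being selected — the encounter is "owned" by the selector. The alternative
(both sides learn) is available as `bothLearn = TRUE` on `playRound` and
`simulatePHC`, off by default, since one-sided updating is the cleaner
reading of "each agent interacts with a sampled neighbour and updates from
its own feedback".

Defaults: $\alpha = 0.1$, $\delta = 0.01$, both constant (no annealing),
initial policies $1/2$, initial values $0$. The rates are conventional
mid-range choices for tabular learners — large enough that value estimates
track within a few dozen rounds, small enough that policies traverse the
interval in $\sim 1/\delta = 100$ rounds; they can be overridden per agent.

### The differential model

In the small-step limit the expected motion of the policies is linear:
$\dot P = U E P + C$ with $U = \mathrm{diag}(u_1,\dots,u_N)$ and
$C = (c_1,\dots,c_N)^\top$. On the cube this becomes a hybrid system: a
coordinate pinned at a face is frozen whenever the linear field points
outward,
$$\dot p_i = 0 \ \text{ if } (p_i = 0 \wedge G_i \le 0) \vee (p_i = 1 \wedge G_i \ge 0), \qquad \dot p_i = G_i \ \text{ otherwise.}$$
A face point with $G_i = 0$ is matched by both branches; both give
$\dot p_i = 0$, so the ambiguity is harmless and the implementation treats
it as frozen.

## Convergence certification

`classifyGame` runs sufficient conditions in order of increasing cost and
returns a structured verdict with the full eigen evidence attached.

* **`ring-parity`** (rings only). On a directed ring each agent is driven
  only by its right-hand neighbour, and the characteristic equation
  collapses to $\lambda^N = \prod_i u_i$: the spectrum is the set of $N$-th
  roots of the curvature product. Pure imaginary roots exist exactly when
  $N \equiv 0 \pmod 4$ with $\prod u_i > 0$, or $N \equiv 2 \pmod 4$ with
  $\prod u_i < 0$. If additionally no agent has a dominant strategy
  (characterised by $(r^{11}-r^{21})(r^{12}-r^{22}) < 0$), each
  $p_i^* = -c_i/u_i$ lies strictly inside $(0,1)$, supplying the interior
  rest point — a complete non-convergence certificate with no eigensolver.
  `ringEigenResidual` checks the root law numerically on demand.
* **`symmetric`**. A symmetric $UE$ has a real spectrum, which rules out
  rotation; every start settles, either at a stable rest point or on a face
  where the outward field is frozen. Checked first among the general rules
  because it needs no spectrum.
* **`hurwitz`**. All eigenvalues with strictly negative real part *and* an
  interior rest point: the rest point is then globally attracting. Both
  conditions are required — matrix stability alone is deliberately not
  certified. A structural note: a game-derived $UE = \mathrm{diag}(u)E$
  always has zero trace (the diagonal of $E$ is zero), so its eigenvalues
  sum to zero and can never all have negative real part. The rule is
  therefore reachable only for models assembled directly from matrices
  (`linearModel(UE, C)`); for genuine games, convergence certificates come
  from symmetry or the ring rule.
* **`imaginary-pair`**. An interior rest point plus a conjugate pure
  imaginary pair $\pm\beta i$: starts near the rest point in the plane
  spanned by the real and imaginary parts of the pair's eigenvector rotate
  forever with angular frequency $\beta$; starts with extra components
  along stable directions spiral onto that cyclic set, which still precludes
  convergence to a point. The returned witness basis spans the cyclic plane
  (orthonormalised); simulation witnesses are drawn from this plane only,
  because it suffices and keeps probes away from the clipping boundary.

Everything else is `INDETERMINATE`: the certificates are sufficient
conditions, and the package does not pretend to a dichotomy. Convergence
rules run before the non-convergence rule because they certify *every*
start, whereas the imaginary pair only asserts existence of a cycling set.

### Numerical tolerances

Exact zeros are measure-zero in floating point, so "zero real part" is a
band: an eigenvalue is neutral when
$|\mathrm{Re}\,\lambda| \le 10^{-9}\max(1, \rho(UE))$. The scale-relative
band keeps the worked cycling example detected while leaving generic
spectra untouched. Symmetry is $\|UE - UE^\top\|_{\max} \le 10^{-12}
\max(1, \|UE\|_{\max})$. Every eigenpair must satisfy
$\|UE v - \lambda v\| \le 10^{-8}\|v\|$ or classification aborts. Rest
points are computed by SVD: the minimum-norm particular solution of
$UE\,P = -C$ is returned, with the null-space dimension reported when the
solution is an affine family (the worked cycling example is such a case:
rank 2, representative $(\tfrac12,\tfrac12,\tfrac12,\tfrac12)$), and
"no rest point" when the drift leaves the column space.

## Integration

`integrateFlow` uses projected explicit Euler as the reference scheme:
advance with the raw linear field, clip to the cube. In the small-step limit
this realises the freezing rule exactly, and a clipped coordinate re-enters
the interior as soon as the field points inward — no event detection is
needed. The default step is $10^{-3}$.

A classical 4th-order step with the same per-step clipping is available as
`method = "rk4"`. On the boundary the projection invalidates classical
order analysis (which is why Euler remains the reference), but for long
*interior* integrations the 4th-order scheme is strongly preferable: the
first-order scheme adds numerical dissipation/anti-dissipation of relative
size $\approx \beta^2 h/2$ per unit time on a rotation of frequency
$\beta$. Concretely, on the worked cycling example ($\beta = 2$) Euler at
$h = 10^{-3}$ inflates the orbit radius by about 6.5% over ten periods,
while the 4th-order scheme closes the orbit to $\sim 10^{-10}$; the orbit
tests therefore use `rk4`.

The closed form $P(t) = e^{tUE}(P_0 - P^*) + P^*$ (`unconstrainedSolution`,
dense matrix exponential, never clipped) serves as the independent oracle.
The projected scheme is validated against it on trajectories that keep a
margin of $10h$ from the boundary, where the two must agree to the scheme's
order; the test suite verifies first-order convergence (errors halve with
the step) and agreement within $10^{-4}(1+\|P_0\|)$ at a resolved step of
$10^{-4}$. A caveat documented deliberately: because game systems have zero
trace, random games always possess expanding directions, and draws with
expanding complex pairs amplify the first-order error constant — at
$h = 10^{-3}$ a minority of random interior probes miss the $10^{-4}$ band
even though the scheme converges at its nominal order. Interior probes use
amplitude 0.05 around a rest point, the same probe scale the witness
validation uses.

`integrateEnsemble` batches many starts through one matrix multiply per
step for convergence surveys, and `integrateFlow(..., frozen = k)` holds
chosen coordinates constant, which is how the ring cascade property
(freezing one agent collapses the whole ring to convergence, one neighbour
at a time) is probed. Note the cascade's *rate* is set by the terminal
drives $|u_i p_{i+1}^* + c_i|$: a draw in which some agent's terminal drive
is $\sim 10^{-3}$ needs $\sim 10^3$ time units to finish sliding, so
finite-horizon convergence surveys can undercount converged systems. The
test suite uses horizon 200 for these surveys and records one such slow
draw among its fixed-seed ring sample.

## The convergence monitor

`simulatePHC` flags a run converged when the maximum absolute policy change
stays below $10^{-4}$ for 1000 consecutive rounds, and by default stops
early. This detects a *quiet window*. For games that settle at a pure
profile, quiet is convergence. Cycling populations, however, also dwell at
cube corners for long stretches while value estimates drift toward the next
preference flip, so the monitor alone would misread limit cycles.
`compareDynamics` therefore judges the stochastic engine by terminal
dispersion — every policy's standard deviation over the final fifth of the
run below 0.05 — which cleanly separates locking (sd $\approx 0$) from
cycling (sd $\approx 0.5$). A related stochastic effect worth knowing: a
cycling population can occasionally be absorbed at a corner where the
unplayed action's value estimate ties or trails forever; this is a genuine
absorbing trap of the finite-$\delta$ learner, not a bug, and it is why
seed-ensemble statements about cycling are majority statements.

## The synthetic-data generator

`randomGame` draws payoff entries uniformly on $[-1, 1]$ (the least
informative choice on a bounded range; configurable) and builds either a
dense network (positive uniform weights, zero diagonal, rows normalised) or
the deterministic ring. Weight matrices supplied by the user are validated,
never silently rescaled (`normalize = TRUE` rescales explicitly). A rest
point can be *planted* at a chosen interior profile: the generator shifts
each agent's $r^{12}$ and $r^{21}$ oppositely, which sets the drift to the
required $c = -(UE P^*)$ while provably leaving every curvature — and hence
$UE$ itself — untouched. Planting is the reference construction for
experiments that need guaranteed interior rest points, since for dense
random draws the min-norm solution of $UE P = -C$ lands inside $(0,1)^N$
only rarely.

What the generator emulates is the model's own world: fixed payoffs, a
static network, homogeneous learning rates. Real cell populations have
none of these guarantees — payoff noise, birth/death, time-varying
contact structure, heterogeneous adaptation — so passing tests certify the
mathematics of the model, not biological fidelity.

## Study sizes

The test suite runs at desk scale, chosen to keep the full suite under a
few minutes while leaving the statistics meaningful: 20 seeds per game for
the stochastic consistency checks ($5\times 10^4$ rounds each, dispersion
measured over the final $10^4$), 100 random starts for the convergence
survey of the symmetric worked example, 200 ring draws with
$N \in \{3,\dots,8\}$ for the root law, 20 frozen-agent and 10
dominant-strategy ring draws at horizon 200, and 50 planted-rest-point
games for the oracle comparison.

## Known limitations

* The certificates are one-directional; `INDETERMINATE` is a statement of
  honesty, not of undecidability.
* Two actions per agent only; no per-encounter payoff noise; static graphs.
* The projected Euler reference scheme is first-order, and its error
  constant grows on expanding draws (see above); use `rk4` or a smaller
  step for precision work in the interior.
* The quiet monitor is a stopping heuristic, not an oscillation test.
* Boundary sliding is realised by clipping, not by a Filippov-type solver;
  events are resolved to one step.
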