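#' Interior fixed point of the linear learning dynamics
#'
#' Solves `UE %*% P = -C`. For an invertible system the unique solution is
#' returned; for a singular but consistent system the minimum-norm solution
#' is returned as the representative of the affine solution family, together
#' with the null-space dimension; an inconsistent system has no rest point.
#'
#' @param model a [LinearModel].
#' @param tol relative residual tolerance for consistency.
#' @return list with
#'   \describe{
#'     \item{point}{the solution (or representative), or `NULL` when none exists}
#'     \item{exists}{logical, a rest point exists}
#'     \item{interior}{logical, `point` lies strictly inside `(0, 1)^N`}
#'     \item{status}{`"interior"`, `"outside"`, `"degenerate"` (solution
#'       family; see `interior` for the representative) or `"inconsistent"`}
#'     \item{nullDim}{dimension of the null space of UE}
#'     \item{residual}{Euclidean norm of `UE %*% point + C`}
#'   }
#' @examples
#' interiorFixedPoint(linearModel(gameFixture("game1_nonconvergent")))$point
#' @export
interiorFixedPoint <- function(model, tol = 1e-8) {
  stopifnot(is(model, "LinearModel"))
  ps <- .particularSolution(model@UE, model@drift)
  if (ps$residual > tol * (1 + sqrt(sum(model@drift^2))))
    return(list(point = NULL, exists = FALSE, interior = FALSE,
                status = "inconsistent", nullDim = ps$nullDim,
                residual = ps$residual))
  inter <- all(ps$point > 0) && all(ps$point < 1)
  status <- if (ps$nullDim > 0L) "degenerate" else if (inter) "interior" else "outside"
  list(point = ps$point, exists = TRUE, interior = inter, status = status,
       nullDim = ps$nullDim, residual = ps$residual)
}

#' Eigen classification of the system matrix
#'
#' Full spectrum of `UE` with each eigenvalue labelled by the sign of its
#' real part; an eigenvalue counts as neutral (zero real part) when
#' `|Re(lambda)| <= zeroTol * max(1, spectral radius)`. Exact zeros are
#' measure-zero in floating point, so the scale-relative band is what makes
#' pure rotation detectable at all; the default keeps generic spectra
#' unaffected.
#'
#' @param model a [LinearModel].
#' @param zeroTol relative width of the neutral band.
#' @return an [EigenStructure].
#' @examples
#' eigenClassify(linearModel(gameFixture("game1_nonconvergent")))
#' @export
eigenClassify <- function(model, zeroTol = 1e-9) {
  stopifnot(is(model, "LinearModel"))
  eig <- eigen(model@UE)
  val <- as.complex(eig$values)
  vec <- matrix(as.complex(eig$vectors), nrow = nrow(model@UE))
  nrm <- sqrt(colSums(Mod(vec)^2))
  vec <- sweep(vec, 2L, nrm, "/")
  res <- vapply(seq_along(val), function(k)
    sqrt(sum(Mod(model@UE %*% vec[, k] - val[k] * vec[, k])^2)), numeric(1))
  if (any(res > 1e-8))
    stop("eigen decomposition failed the residual check (max residual ",
         format(max(res)), ")")
  band <- zeroTol * max(1, max(Mod(val)))
  lab <- ifelse(abs(Re(val)) <= band, "neutral",
                ifelse(Re(val) < 0, "stable", "unstable"))
  new("EigenStructure", values = val, vectors = vec, labels = lab,
      zeroTol = zeroTol)
}

## Real orthonormal basis of the plane spanned by Re(v), Im(v).
.cyclicPlane <- function(v) {
  B <- cbind(Re(v), Im(v))
  qr.Q(qr(B))[, 1:2, drop = FALSE]
}

## Real basis of the span of a set of (possibly complex) eigenvectors.
.realSpan <- function(vecs) {
  if (!ncol(vecs)) return(matrix(numeric(0), nrow = nrow(vecs), ncol = 0))
  B <- cbind(Re(vecs), Im(vecs))
  qrB <- qr(B)
  qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE]
}

#' Sufficient non-convergence certificate
#'
#' Fires iff (a) a rest point of the linear flow exists with a representative
#' strictly inside `(0, 1)^N` and (b) the spectrum contains a conjugate pure
#' imaginary pair (zero real part, nonzero imaginary part). Trajectories
#' started near the fixed point inside the plane spanned by the pair's
#' eigenvector rotate forever with angular frequency `|Im(lambda)|`; starts
#' with additional components along the stable directions spiral onto that
#' cyclic set, so they do not converge to a point either.
#'
#' @param model a [LinearModel].
#' @param zeroTol neutral-band tolerance passed to [eigenClassify()].
#' @return `NULL` when the certificate does not apply, else a list with
#'   `fixedPoint`, `witnessBasis` (orthonormal N x 2 basis of the cyclic
#'   plane), `frequency` (angular frequency of the rotation), `stableBasis`
#'   (real basis of the stable directions) and `eigen`.
#' @export
checkNonconvergence <- function(model, zeroTol = 1e-9) {
  stopifnot(is(model, "LinearModel"))
  fp <- interiorFixedPoint(model)
  if (!fp$exists || !fp$interior) return(NULL)
  es <- eigenClassify(model, zeroTol)
  band <- zeroTol * max(1, max(Mod(es@values)))
  cand <- which(es@labels == "neutral" & abs(Im(es@values)) > band)
  if (!length(cand)) return(NULL)
  k <- cand[which.max(abs(Im(es@values[cand])))]
  list(fixedPoint = fp$point,
       witnessBasis = .cyclicPlane(es@vectors[, k]),
       frequency = abs(Im(es@values[k])),
       stableBasis = .realSpan(es@vectors[, es@labels == "stable", drop = FALSE]),
       eigen = es)
}

#' Sufficient convergence certificate
#'
#' Two rules, tried in order. `"symmetric"`: a symmetric `UE` has a real
#' spectrum, which rules out rotation; every start then converges (to the
#' rest point if it is stable, otherwise to a face of the cube where the
#' outward field is frozen). It is checked first because it needs no
#' spectrum. `"hurwitz"`: every eigenvalue has strictly negative real part
#' *and* an interior rest point exists, making that rest point globally
#' attracting; both conditions are required — stability of the matrix alone
#' is not certified here.
#'
#' @param model a [LinearModel].
#' @param zeroTol neutral-band tolerance.
#' @return `"symmetric"`, `"hurwitz"`, or `NULL` when neither rule applies.
#' @export
checkConvergence <- function(model, zeroTol = 1e-9) {
  stopifnot(is(model, "LinearModel"))
  UE <- model@UE
  sc <- max(abs(UE))
  if (max(abs(UE - t(UE))) <= 1e-12 * max(1, sc)) return("symmetric")
  es <- eigenClassify(model, zeroTol)
  if (all(es@labels == "stable")) {
    fp <- interiorFixedPoint(model)
    if (fp$exists && fp$interior) return("hurwitz")
  }
  NULL
}

#' Dominant strategy of a 2x2 payoff matrix
#'
#' Action 1 is (weakly) dominant when it does at least as well as action 2
#' against both opponent actions, strictly better against at least one;
#' symmetrically for action 2. No action dominates exactly when
#' `(r11 - r21) * (r12 - r22) < 0`. A matrix whose two rows are identical is
#' degenerate (both actions always tie).
#'
#' @param R numeric 2x2 payoff matrix.
#' @return `"action1"`, `"action2"`, `"none"`, or `"degenerate"`.
#' @examples
#' dominantStrategy(diag(2))                        # "none"
#' dominantStrategy(matrix(c(2, 0, 2, 0), 2, 2))    # "action1"
#' @export
dominantStrategy <- function(R) {
  R <- as.matrix(R)
  if (!all(is.finite(R)) || !all(dim(R) == 2L)) stop("R must be a finite 2x2 matrix")
  d1 <- R[1, 1] - R[2, 1]
  d2 <- R[1, 2] - R[2, 2]
  if (d1 == 0 && d2 == 0) return("degenerate")
  if (d1 >= 0 && d2 >= 0) return("action1")
  if (d1 <= 0 && d2 <= 0) return("action2")
  "none"
}

#' Ring parity/sign non-convergence certificate
#'
#' On a directed ring each agent is driven only by its right-hand neighbour
#' and the characteristic equation of `UE` collapses to
#' `lambda^N = prod(u_i)`: the eigenvalues are the N-th roots of the product
#' of the curvatures. A pure imaginary pair therefore exists exactly when
#' the roots include `+/- i |prod u|^(1/N)`, i.e. when `N` is divisible by 4
#' with `prod(u) > 0`, or `N = 4k + 2` with `prod(u) < 0`. When additionally
#' no agent has a dominant strategy, each `p_i* = -c_i / u_i` lies strictly
#' in (0, 1), giving the interior fixed point that completes the
#' non-convergence certificate — all without computing a spectrum of a large
#' matrix (the numeric pair is still located and returned as evidence).
#'
#' @param game a [SocialGame] with ring topology.
#' @return list with `fires` (logical), `reason` (character), and when it
#'   fires also `fixedPoint`, `productU`, `eigenPair` (the numerically
#'   located conjugate pair) and `witnessBasis`. `reason = "inapplicable"`
#'   flags a zero curvature that makes the sign rule meaningless.
#' @export
ringNonconvergence <- function(game) {
  stopifnot(is(game, "SocialGame"))
  if (!isRing(game)) stop("ringNonconvergence requires a ring topology (see isRing)")
  n <- nAgents(game)
  dom <- vapply(game@payoffs, dominantStrategy, character(1))
  if (any(dom != "none"))
    return(list(fires = FALSE,
                reason = sprintf("agent %d has a dominant strategy (%s)",
                                 which(dom != "none")[1L], dom[dom != "none"][1L])))
  u <- curvatures(game)
  if (any(u == 0)) return(list(fires = FALSE, reason = "inapplicable"))
  pu <- prod(u)
  hit <- (n %% 4L == 0L && pu > 0) || (n %% 4L == 2L && pu < 0)
  if (!hit)
    return(list(fires = FALSE,
                reason = sprintf("parity/sign condition unmet (N = %d, prod(u) = %g)", n, pu)))
  cc <- vapply(game@payoffs, function(R) deriveUC(R)[["c"]], numeric(1))
  fp <- -cc / u
  model <- linearModel(game)
  es <- eigenClassify(model)
  band <- es@zeroTol * max(1, max(Mod(es@values)))
  cand <- which(abs(Re(es@values)) <= band & Im(es@values) > band)
  k <- cand[which.max(Im(es@values[cand]))]
  list(fires = TRUE, reason = "ring-parity", fixedPoint = fp, productU = pu,
       eigenPair = c(es@values[k], Conj(es@values[k])),
       witnessBasis = .cyclicPlane(es@vectors[, k]))
}

#' Diagnostic for the ring spectral identity
#'
#' Every eigenvalue of a ring system matrix satisfies
#' `lambda^N = prod(u_i)` (companion structure of the cyclic coupling).
#' Returns the worst violation over the numerically computed spectrum,
#' `max_k |lambda_k^N - prod(u_i)|`, which should be at rounding level.
#'
#' @param game a [SocialGame] with ring topology.
#' @return numeric scalar residual.
#' @export
ringEigenResidual <- function(game) {
  stopifnot(is(game, "SocialGame"))
  if (!isRing(game)) stop("ringEigenResidual requires a ring topology")
  u <- curvatures(game)
  es <- eigenClassify(linearModel(game))
  max(Mod(es@values^nAgents(game) - prod(u)))
}

#' Classify the learning dynamics of a game
#'
#' Runs the certificates in order of increasing cost: the ring parity rule
#' when the topology is a ring, then the convergence rules (symmetric, then
#' hurwitz), then the general pure-imaginary-pair non-convergence rule.
#' Convergence rules come before the non-convergence rule because they
#' certify *every* start, whereas non-convergence only asserts the existence
#' of a cycling set of starts. Anything unmatched is `INDETERMINATE` — the
#' certificates are sufficient conditions, not a dichotomy — with the full
#' eigen evidence attached.
#'
#' @param game a [SocialGame].
#' @param zeroTol neutral-band tolerance for the spectral tests.
#' @return a [ConvergenceVerdict].
#' @examples
#' classifyGame(gameFixture("game1_nonconvergent"))
#' classifyGame(gameFixture("game2_convergent"))
#' @export
classifyGame <- function(game, zeroTol = 1e-9) {
  stopifnot(is(game, "SocialGame"))
  model <- linearModel(game)
  es <- eigenClassify(model, zeroTol)
  emptyBasis <- matrix(numeric(0), nrow = nAgents(game), ncol = 0)
  if (isRing(game)) {
    rw <- ringNonconvergence(game)
    if (isTRUE(rw$fires))
      return(new("ConvergenceVerdict", verdict = "NONCONVERGENT_SET_EXISTS",
                 firedRule = "ring-parity", fixedPoint = rw$fixedPoint,
                 witnessBasis = rw$witnessBasis, eigen = es,
                 evidence = list(productU = rw$productU, eigenPair = rw$eigenPair)))
  }
  rule <- checkConvergence(model, zeroTol)
  if (!is.null(rule)) {
    fp <- interiorFixedPoint(model)
    return(new("ConvergenceVerdict", verdict = "CONVERGES_ALL", firedRule = rule,
               fixedPoint = if (fp$exists && fp$interior) fp$point else numeric(0),
               witnessBasis = emptyBasis, eigen = es, evidence = list()))
  }
  w <- checkNonconvergence(model, zeroTol)
  if (!is.null(w))
    return(new("ConvergenceVerdict", verdict = "NONCONVERGENT_SET_EXISTS",
               firedRule = "imaginary-pair", fixedPoint = w$fixedPoint,
               witnessBasis = w$witnessBasis, eigen = es,
               evidence = list(frequency = w$frequency, stableBasis = w$stableBasis)))
  fp <- interiorFixedPoint(model)
  new("ConvergenceVerdict", verdict = "INDETERMINATE", firedRule = "none",
      fixedPoint = if (fp$exists && fp$interior) fp$point else numeric(0),
      witnessBasis = emptyBasis, eigen = es,
      evidence = list(fixedPointStatus = fp$status))
}
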