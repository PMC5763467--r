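#' @describeIn SocialGame-class compact display
#' @param object object to display
#' @export
setMethod("show", "SocialGame", function(object) {
  n <- nAgents(object)
  cat(sprintf("SocialGame with %d agents (%s topology)\n", n,
              if (isRing(object)) "ring" else "weighted"))
  u <- curvatures(object)
  cat("  curvatures u:", paste(format(u, digits = 4), collapse = " "), "\n")
})

#' @describeIn LinearModel-class compact display
#' @param object object to display
#' @export
setMethod("show", "LinearModel", function(object) {
  cat(sprintf("LinearModel dP/dt = UE P + C on [0,1]^%d\n", nAgents(object)))
  cat("  UE:\n")
  print(round(object@UE, 6))
  cat("  C: ", paste(format(object@drift, digits = 6), collapse = " "), "\n")
})

#' @describeIn EigenStructure-class compact display
#' @param object object to display
#' @export
setMethod("show", "EigenStructure", function(object) {
  cat("EigenStructure:\n")
  for (k in seq_along(object@values))
    cat(sprintf("  %s  (%s)\n", format(object@values[k], digits = 6),
                object@labels[k]))
})

#' @describeIn ConvergenceVerdict-class compact display
#' @param object object to display
#' @export
setMethod("show", "ConvergenceVerdict", function(object) {
  cat(sprintf("ConvergenceVerdict: %s (rule: %s)\n", object@verdict, object@firedRule))
  if (length(object@fixedPoint))
    cat("  fixed point:", paste(format(object@fixedPoint, digits = 6), collapse = " "), "\n")
  cat("  eigenvalues:",
      paste(format(object@eigen@values, digits = 4), collapse = ", "), "\n")
})

#' @describeIn Trajectory-class compact display
#' @param object object to display
#' @export
setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d recorded states over t in [0, %g], %d agents\n",
              length(object@times), max(object@times), ncol(object@states)))
})

#' @describeIn PHCSim-class compact display
#' @param object object to display
#' @export
setMethod("show", "PHCSim", function(object) {
  cat(sprintf("PHCSim: %d recorded rounds (last %d), %d agents\n",
              length(object@rounds), max(object@rounds), ncol(object@policies)))
  cat(sprintf("  converged: %s%s\n", object@converged,
              if (isTRUE(object@converged)) sprintf(" (round %d)", object@convergedRound) else ""))
  cat("  final policies:",
      paste(format(object@finalPolicies, digits = 4), collapse = " "), "\n")
})
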