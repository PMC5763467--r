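#' Read a game specification file
#'
#' The on-disk format is a JSON object
#' `{"agents": [{"payoff": [[r11, r12], [r21, r22]]}, ...], "E": [[...]]}`.
#' Shapes are checked strictly: every agent entry must carry exactly a 2x2
#' `payoff` (per-edge payoff tables are reserved in the format but rejected by
#' the engine), and `E` must be square with one row per agent. All
#' [SocialGame] invariants (row sums, zero diagonal, entry range) are enforced
#' on load. Values representable in double precision round-trip bit-exactly
#' through [writeGame()].
#'
#' @param path path to a JSON game file.
#' @param normalize logical, rescale weight rows to sum to 1 instead of
#'   rejecting them (see [socialGame()]).
#' @return a [SocialGame].
#' @seealso [writeGame()], [gameFixture()]
#' @export
readGame <- function(path, normalize = FALSE) {
  if (!file.exists(path)) stop("game file not found: ", path)
  spec <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                   error = function(e) stop("malformed JSON in ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
  if (!is.list(spec) || is.null(spec$agents) || is.null(spec$E))
    stop("game file must contain 'agents' and 'E'")
  payoffs <- lapply(seq_along(spec$agents), function(i) {
    a <- spec$agents[[i]]
    extra <- setdiff(names(a), "payoff")
    if (length(extra))
      stop(sprintf("agent %d: unsupported field(s) %s (per-edge payoffs are not supported)",
                   i, paste(sQuote(extra), collapse = ", ")))
    p <- a$payoff
    if (!is.list(p) || length(p) != 2L || any(lengths(p) != 2L))
      stop(sprintf("agent %d: 'payoff' must be a 2x2 matrix", i))
    matrix(as.numeric(unlist(p)), 2, 2, byrow = TRUE)
  })
  E <- spec$E
  if (!is.list(E) || any(lengths(E) != length(E)))
    stop("'E' must be a square matrix")
  E <- do.call(rbind, lapply(E, function(r) as.numeric(unlist(r))))
  socialGame(payoffs, E, normalize = normalize)
}

#' Write a game specification file
#'
#' Inverse of [readGame()]; numbers are serialized at full double precision so
#' load -> save -> load yields an identical game.
#'
#' @param game a [SocialGame].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGame <- function(game, path) {
  stopifnot(is(game, "SocialGame"))
  spec <- list(
    agents = lapply(game@payoffs, function(R) list(payoff = unname(R))),
    E = unname(game@weights)
  )
  json <- jsonlite::toJSON(spec, digits = I(17), auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Packaged worked-example games
#'
#' Two four-agent games on the same bipartite interaction network
#' (`E[i, j] = 1/2` for the two cross-group partners). In
#' `"game1_nonconvergent"` agents 1 and 3 play a coordination payoff
#' (identity matrix) while agents 2 and 4 play the anti-coordination payoff
#' `[[0, 1], [1, 0]]`; the resulting system matrix has a pure imaginary
#' eigenvalue pair and the learning dynamics cycle forever around the mixed
#' fixed point (1/2, 1/2, 1/2, 1/2). In `"game2_convergent"` all four agents
#' play the coordination payoff; the system matrix is symmetric and every
#' start converges.
#'
#' @param name `"game1_nonconvergent"` or `"game2_convergent"`.
#' @return a [SocialGame].
#' @examples
#' classifyGame(gameFixture("game2_convergent"))
#' @export
gameFixture <- function(name = c("game1_nonconvergent", "game2_convergent")) {
  name <- match.arg(name)
  readGame(system.file("extdata", paste0(name, ".json"), package = "cellswarm",
                       mustWork = TRUE))
}

#' Write a trajectory as CSV
#'
#' One row per recorded time point / round, columns `t,p_1,...,p_N` for a
#' [Trajectory] or `round,p_1,...,p_N` for a [PHCSim]. Numbers are written
#' with 17 significant digits so re-runs are byte-identical.
#'
#' @param x a [Trajectory] or [PHCSim].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(x, path) {
  if (is(x, "Trajectory")) {
    first <- "t"; idx <- x@times; S <- x@states
  } else if (is(x, "PHCSim")) {
    first <- "round"; idx <- x@rounds; S <- x@policies
  } else stop("x must be a Trajectory or PHCSim")
  header <- c(first, paste0("p_", seq_len(ncol(S))))
  rows <- cbind(format(idx, digits = 17, trim = TRUE, scientific = FALSE),
                matrix(format(S, digits = 17, trim = TRUE), nrow = nrow(S)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  writeLines(apply(rows, 1L, paste, collapse = ","), con)
  invisible(path)
}
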