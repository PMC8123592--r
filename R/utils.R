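#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state, so deterministic sub-draws (donor baselines,
#' stain noise) never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and a stream label
#'
#' Independent sub-streams (per stain, per scene, per model) are derived
#' deterministically so that one master seed fixes the whole experiment.
#' Kept strictly below 2^31.
#'
#' @param seed parent integer seed.
#' @param ... integers or strings identifying the sub-stream.
#' @return integer seed.
#' @keywords internal
child_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) utf8ToInt(p) else as.integer(p)
  }))
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    h <- (h * 69069 + as.double(p) + 1) %% 2147483647
  }
  as.integer(h)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
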