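# Seed plumbing. Every stochastic operation takes an explicit seed argument;
# nothing reads ambient random state unless seed = NULL is passed deliberately.

# Set the RNG seed for the calling frame and restore the previous state on exit.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  expr <- if (has_old) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(NULL)
}

#' Derive a reproducible sub-seed
#'
#' Mixes a base seed with integer stream labels into a new seed below `2^31`,
#' so that each stage of a pipeline (network generation, truth draws, design
#' Monte Carlo, evaluation rollouts) gets its own named, replayable stream.
#'
#' @param seed non-negative integer base seed.
#' @param ... integer stream labels.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (x in parts) {
    # multiplier keeps h*69069 + x + 1 exactly representable in doubles
    h <- (h * 69069 + as.numeric(x) + 1) %% 2147483647
  }
  as.integer(h)
}
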