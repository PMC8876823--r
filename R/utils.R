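# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded subroutines (fold shuffles, noise matrices)
#' never perturb an enclosing stochastic algorithm's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a reproducible sub-seed from a seed and a string tag
#'
#' Polynomial rolling hash of `tag` folded into `seed`, reduced modulo
#' 2^31 - 1 so the result is a valid 32-bit R seed. Used for seed fan-out:
#' each (preprocessing, selector, mode) grid cell gets its own stream, so
#' results do not shift when the grid is reordered.
#'
#' @param seed integer base seed.
#' @param tag character scalar.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, tag) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(tag)) h <- (h * 131 + b) %% m
  as.integer(h)
}

stop_fluortea <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fluortea_error")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L &&
  is.finite(x) && x == round(x)
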