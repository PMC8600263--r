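## Internal helpers shared across modules.

#' Derive reproducible sub-seeds from a single master seed
#'
#' One integer seed governs a whole pipeline run; every stage that consumes
#' randomness (cohort simulation, train/test split, K-means restarts, CV fold
#' assignment) draws its own seed from this stream so that stages stay
#' reproducible independently of how many random numbers each one uses.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
spawn_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.numeric(n), n >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, as.integer(n))
}

## Save/restore .Random.seed so library internals never perturb user RNG flow.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

## Evaluate `expr` under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Structured one-line stage log to stderr (quiet unless option set).
pct_log <- function(stage, ...) {
  if (isTRUE(getOption("pascrosstalk.verbose", FALSE))) {
    message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
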