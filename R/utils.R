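## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' then restores the previous RNG state so callers never perturb the
#' session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic integer hashing over a prime modulus below 2^31, kept in
## doubles so intermediate products (< 2^53) stay exact.
.hash_mod <- 2147483629

hash_mix <- function(h, v) {
  (h * 31 + v) %% .hash_mod
}

hash_tuple <- function(...) {
  vals <- c(...)
  h <- 17
  for (v in vals) h <- hash_mix(h, v)
  h
}

## Stops with a clean message unless condition holds.
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
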