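#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards so that seeded operations do
#' not perturb unrelated randomness.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a stream of child seeds from a master seed
#'
#' Child seeds keep independent analyses reproducible under a single
#' user-supplied seed. All values stay below 2^31 - 1.
#'
#' @keywords internal
#' @noRd
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
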