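#' @keywords internal
clamp01 <- function(x) pmin(pmax(x, 0), 1)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a parent seed
#'
#' Deterministic integer mixing so that any subject or trial can be re-run in
#' isolation: subject seeds derive from the master seed, trial seeds from the
#' subject seed and trial index. Results stay below 2^31.
#'
#' @param seed parent seed (integer)
#' @param index child index (integer >= 0)
#' @return an integer seed
#' @export
derive_seed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 7919 + 12345) %% 2147483563
  as.integer(s) + 1L
}

## modulus arithmetic above stays in double precision; 48271 * 2^31 < 2^53
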