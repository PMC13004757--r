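# Local RNG scoping: evaluate expr with a given seed without disturbing
# the caller's RNG state. All stochastic operations in the package funnel
# through this (or pass explicit seeds to the C++ engine).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Derive a stream of child seeds from one master seed
#'
#' Deterministic expansion of one integer seed into `n` child seeds
#' (all below 2^31), used to give repetitions and subsystems
#' independent but reproducible randomness.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @param salt integer stream selector.
#' @return Numeric vector of `n` seeds.
#' @export
derive_seeds <- function(seed, n, salt = 0L) {
  (as.double(seed) * 48271 + salt * 16807 + seq_len(n) * 69621) %% 2147483629
}
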