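#' Derive a named child seed from a parent seed
#'
#' Every stochastic operation in the package draws from its own named
#' stream derived from the caller's seed, so that adding or reordering
#' one randomized step never perturbs another. The derivation is a small
#' string hash folded into the 31-bit positive integer range.
#'
#' @param seed parent integer seed.
#' @param name stream name (e.g. `"deviant_placement"`).
#' @return A positive integer seed.
#' @export
child_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so no package operation reads or clobbers global
#' random state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
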