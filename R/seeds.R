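#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic operation in the package takes an explicit seed.  A
#' run-level master seed is expanded into per-stage child seeds with a
#' deterministic integer recurrence, so that independent pipeline stages use
#' decorrelated RNG streams while the whole run stays reproducible from a
#' single integer.
#'
#' @param master integer master seed.
#' @param stage stage index (integer) or stage name (character); names are
#'   hashed to an integer offset.
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @examples
#' child_seed(1, "simulate")
#' child_seed(1, 2L)
#' @export
child_seed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master))
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  m <- 2147483647  # 2^31 - 1, Mersenne prime as in the Lehmer generator
  x <- (abs(as.numeric(master)) %% m)
  x <- (x * 48271 + as.numeric(stage) * 16807 + 1) %% m
  x <- (x * 48271 + 1) %% m
  as.integer(x)
}

# run fn with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, fn) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  fn()
}
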