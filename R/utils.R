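#' Derive a stage seed from a master seed
#'
#' All stochastic operations in the package take an explicit seed. Pipelines
#' derive per-stage seeds from a single master seed with this helper so that
#' stages remain independently reproducible. Result is kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage integer stage index (>= 0).
#' @return integer seed.
#' @export
stage_seed <- function(master, stage) {
  master <- as.double(master)
  stage <- as.double(stage)
  as.integer((master * 48271 + stage * 7919 + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a function under a local RNG state
#'
#' Runs `fn()` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded operations do not disturb the surrounding
#' random stream. `seed = NULL` uses the current stream unchanged.
#'
#' @param seed integer seed or NULL.
#' @param fn zero-argument function.
#' @return the value of `fn()`.
#' @export
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
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
  fn()
}
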