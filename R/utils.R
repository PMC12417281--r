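# Internal seeding helpers. All stochastic entry points take an explicit seed;
# child seeds are derived deterministically so one master seed fixes every
# stage of a run without coupling their RNG streams.

withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a child seed from a master seed
#'
#' Deterministic seed derivation used throughout the package so one master
#' seed fixes every stage of a run (cohort, raters, training, prediction)
#' without coupling their RNG streams. Results stay below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param offset integer stage offset.
#' @return derived integer seed.
#' @examples
#' deriveSeed(1L, 31L)
#' @export
deriveSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + as.double(offset) * 9973 + 1) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
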