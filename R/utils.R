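#' Derive a reproducible child seed from a global seed
#'
#' A single pipeline seed fans out into per-component seeds so that each
#' stochastic stage (genome simulation, trait simulation, permutations,
#' bootstrap) can be regenerated independently of the others.
#'
#' @param seed integer global seed.
#' @param tag character label of the component.
#' @return An integer seed in `[1, 2^31 - 2]`, a deterministic function of
#'   `seed` and `tag`.
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 2654435.0)
  as.integer((abs(seed) * 69069 + h) %% (2^31 - 3) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## run expr under a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}
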