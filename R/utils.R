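# Small shared helpers.

#' Evaluate code under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded generators never disturb
#' the caller's RNG stream. All randomised functions in the package take
#' an explicit seed and run through this helper; there is no hidden
#' global state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic derivation `(master * 7919 + stage * 104729 + index)
#' mod (2^31 - 1)`, so a single master seed reproduces every stage of a
#' pipeline run while stages remain statistically decoupled.
#'
#' @param master master integer seed.
#' @param stage small integer stage code.
#' @param index repetition index within a stage.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  as.integer((as.double(master) * 7919 + as.double(stage) * 104729 +
                as.double(index)) %% 2147483647)
}
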