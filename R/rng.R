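# Seed handling: every stochastic operation takes an optional integer seed.
# When a seed is given the global RNG state is saved, the stream is seeded,
# and the previous state restored afterwards, so seeded calls are pure.
local_rng <- function(seed) {
  if (is.null(seed)) return(NULL)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(as.integer(seed))
  list(old = old)
}

restore_rng <- function(state) {
  if (is.null(state)) return(invisible(NULL))
  if (is.null(state$old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state$old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a per-patient seed from a master seed
#'
#' Seed splitting rule used by the cohort generator: patient `i` gets
#' `(master * 1000003 + i) mod (2^31 - 1)`. Documented so that a patient's
#' data can be regenerated in isolation.
#'
#' @param master Master integer seed.
#' @param i Patient index (1-based).
#' @return Integer seed.
#' @export
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 1000003 + as.double(i)) %% 2147483647)
}
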