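#' Derive a reproducible substream seed for a named pipeline stage
#'
#' All stochastic stages draw from a single user-supplied integer seed; each
#' stage hashes its name into an offset so that re-running one stage in
#' isolation reproduces its in-pipeline randomness.
#'
#' @param seed integer master seed.
#' @param stage character stage name (e.g. "simulate", "qc").
#' @return an integer seed < 2^31 suitable for [set.seed()].
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(seed) + h * 2654435L) %% .Machine$integer.max)
}

# run expr under a local RNG state seeded by `seed`, restoring state after
with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  expr
}
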