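#' Derive a named substream seed from a master seed
#'
#' All stochastic stages (prior draws, optimizer restarts, mixture clouds,
#' final resample, simulators) derive their own seed deterministically from a
#' single user seed and a stage name, so that a pipeline run is
#' bit-reproducible while stages remain decoupled.
#'
#' @param seed master integer seed.
#' @param name character stage name, e.g. `"priors"`.
#' @return an integer seed in `[0, 2^31)`.
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 1000003
  as.integer((abs(seed) + h * 2654435.0) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}
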