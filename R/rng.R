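#' Derive a named substream seed
#'
#' All stochastic stages of the pipeline (record matching, subsampling,
#' simulation, data generation) draw from their own substream derived from the
#' single run seed plus a stage name, so each stage is individually
#' reproducible and inserting a new stochastic stage does not shift the draws
#' of the others.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name, e.g. `"match"` or `"subsample"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' stage_seed(1, "match")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147480009 # prime below 2^31
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer((abs(seed) %% m * 69621 + h) %% m + 1)
}

#' Evaluate an expression under a stage-specific RNG substream
#'
#' Sets the RNG to the substream for (`seed`, `stage`), evaluates `expr`, and
#' restores the caller's RNG state afterwards.
#'
#' @inheritParams stage_seed
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_stage_seed <- function(seed, stage, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  expr
}
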