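#' Derive a stage-specific seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own seed deterministically
#' from the global seed and a stage label, so that stages can be re-run in
#' isolation without perturbing each other's random streams.
#'
#' @param seed integer global seed.
#' @param stage character label of the stage (e.g. `"simulate"`).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 7919 + h) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Min-max scale a signal to the interval from -1 to 1
#'
#' Constant signals map to all zeros rather than dividing by zero.
#'
#' @param x numeric vector.
#' @return numeric vector in `[-1, 1]`.
#' @export
minmax_scale <- function(x) {
  r <- range(x, finite = TRUE)
  if (!all(is.finite(r)) || r[2] == r[1]) return(rep(0, length(x)))
  2 * (x - r[1]) / (r[2] - r[1]) - 1
}
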