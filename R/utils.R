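# Internal helpers shared across modules.

config_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("eventsnn_config_error", "error", "condition")))
}

runtime_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("eventsnn_runtime_error", "error", "condition")))
}

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero
#' (`round()` in R rounds half to even). This is the rounding rule used
#' for weight quantization.
#'
#' @param x numeric vector.
#' @return numeric vector of integers.
#' @examples
#' round_half_away(c(0.5, -0.5, 3.5, 2.4))
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == floor(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
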