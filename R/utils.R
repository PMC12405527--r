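#' Derive a reproducible child seed
#'
#' Maps a base seed and a work-unit index to an integer seed below 2^31,
#' so that sweep points and replicate batches each get an independent,
#' order-insensitive random stream.
#'
#' @param seed integer base seed.
#' @param index non-negative integer work-unit index.
#' @return an integer seed in 1..2147483645.
#' @export
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) + 7919 * as.numeric(index)) %% 2147483645
  as.integer(s) + 1L
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

stop_input <- function(...) stop(..., call. = FALSE)

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}
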