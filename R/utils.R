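`%||%` <- function(x, y) if (is.null(x)) y else x

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) if (!isTRUE(cond)) .stopf(fmt, ...)

#' Derive a child seed from a base seed
#'
#' Deterministically maps a base seed and a stream label to a 32-bit seed so
#' that independent pipeline stages draw from independent streams.
#'
#' @param seed integer base seed.
#' @param stream character label of the consuming stage.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stream) {
  .assert(is.numeric(seed) && length(seed) == 1, "seed must be a single number")
  bytes <- utf8ToInt(paste0(stream, ":", format(seed, scientific = FALSE)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Run code with a local RNG state so callers' streams are not disturbed.
.with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
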