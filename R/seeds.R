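#' Derive a child seed from a root seed
#'
#' All generators in the package draw their randomness from a single root
#' seed through this stream-splitting scheme, so each stage of a synthetic
#' study can be regenerated independently of the others. The child seed is a
#' deterministic hash of the root seed and a stream label, kept inside the
#' 32-bit signed-integer range `set.seed()` accepts.
#'
#' @param seed integer root seed.
#' @param stream character label of the stream (e.g. `"anatomy"`,
#'   `"ephys"`).
#' @param index optional integer sub-index (e.g. a unit or dataset number).
#' @return an integer seed.
#' @export
split_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, length(stream) == 1)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  val <- (as.double(seed) * 48271 + h * 7919 + as.double(index) * 104729) %% 2147483629
  as.integer(val)
}
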