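#' Derive a named RNG substream seed from a root seed
#'
#' All randomness in the package flows from one root seed, fanned out into
#' named substreams (landscape, truth, counts, annotation, expression,
#' shuffle, ...) so individual simulation stages can be regenerated
#' independently and deterministically.
#'
#' @param seed integer root seed.
#' @param name substream name (any non-empty string).
#' @return an integer seed strictly below 2^31.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(name),
            nzchar(name))
  chars <- utf8ToInt(name)
  h <- sum(chars * seq_along(chars)) %% 104729
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919 + 17) %% 2147483629)
}

# evaluate code under a substream seed, restoring RNG state afterwards
with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}
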