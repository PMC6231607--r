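#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)
}

# derive a per-unit 32-bit seed from a base seed; keeps streams stable when
# the number of units grows
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) + 7919 * as.double(i)) %% 2147483647)
}
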