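#' @importFrom stats rbinom rlnorm rnorm rpois runif setNames cor fisher.test
#'   hclust dist cutree as.dist
#' @importFrom utils head tail
#' @importFrom methods is
#' @importFrom data.table as.data.table fread fwrite
NULL

# Deterministic 32-bit sub-seed for a named RNG stream. Adding a stream (e.g.
# a new dataset) must not perturb draws made under any other stream name.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h * 69621 + 1) %%
               2147483647)
}

# Run `code` under the RNG stream (seed, name), restoring the caller's RNG.
with_stream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

# 0-based half-open [start, end) -> IRanges (1-based closed).
ir0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# IRanges -> data.frame with 0-based half-open start/end.
from_ir0 <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Random DNA of a given length (uses the current RNG stream).
random_dna <- function(n) {
  intToUtf8(sample(c(65L, 67L, 71L, 84L), n, replace = TRUE))
}

# Reverse complement of an ACGTN string.
revcomp <- function(s) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
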