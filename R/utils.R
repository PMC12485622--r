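# Internal helpers shared across the package.

#' @keywords internal
"_PACKAGE"

# Deterministic substream seed from a master seed and a set of labels.
# Polynomial string hash folded into [1, 2^31 - 2] so every (trait, model,
# partition, chain) cell of a run gets its own reproducible RNG stream.
.substream <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

.msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

# Sample standard deviation guard: returns TRUE when a vector is constant
# to within numerical noise.
.is_constant <- function(x, tol = 1e-12) {
  x <- x[is.finite(x)]
  length(x) < 2L || stats::sd(x) <= tol * max(1, mean(abs(x)))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
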