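#' @keywords internal
"_PACKAGE"

# Bounded derived seeds: keep everything below .Machine$integer.max so
# set.seed() never sees an overflowed value.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x >= 0
}

is_fraction <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Pearson correlation that flags degenerate (zero-variance) inputs instead of
# returning NA from cor().
safe_pearson <- function(x, y) {
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(value = NA_real_, defined = FALSE))
  }
  list(value = stats::cor(x, y), defined = TRUE)
}
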