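stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stopf("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stopf("`%s` must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    stopf("`%s` must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

# Derive a reproducible 32-bit sub-seed from a base seed and an index.
derive_seed <- function(seed, k) {
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L
}
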