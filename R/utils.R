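# internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All exported generators funnel through this so
# a fixed seed is bit-reproducible and never disturbs user code.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a master seed and a stage offset, kept inside the
# 32-bit integer range so it is always a valid `set.seed()` argument.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ccl <- function(...) stop(..., call. = FALSE)
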