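# Internal helpers shared across modules.

# Derive a reproducible child seed from a root seed and a stage label.
# Arithmetic stays below 2^53 so the result is exact in double precision,
# and the output is a strictly positive 32-bit integer.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u)) %% 1048576
  x <- ((seed %% 65536) * 1103515245 + h * 2654435 + (seed %% 2147483647)) %%
    2147483646
  as.integer(x + 1)
}

clip01 <- function(x) pmin(1, pmax(0, x))

stop_if_not_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
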