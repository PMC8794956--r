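# Internal helpers shared across modules.

# Derive a child seed (kept below 2^31) from a base seed and an offset so each
# randomized stage of a pipeline run has its own reproducible stream.
child_seed <- function(seed, offset) {
  ((as.double(seed) %% 2147480000) * 69069 + 12345 + 97 * as.double(offset)) %% 2147483629 + 1
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict_min && x <= min)
    stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  if (!strict_min && x < min)
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  invisible(x)
}

# Half-open interval membership [start, end), the package-wide time convention.
in_interval <- function(t, start, end) t >= start & t < end
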