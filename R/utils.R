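stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, strict = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single non-missing number", name)
  if (integer && x != round(x)) stopf("'%s' must be an integer", name)
  if (strict && x <= lower) stopf("'%s' must be > %s", name, lower)
  if (!strict && x < lower) stopf("'%s' must be >= %s", name, lower)
  x
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream; a NULL seed leaves the stream alone.
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
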