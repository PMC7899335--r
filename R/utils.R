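#' @keywords internal
"_PACKAGE"

## Internal validation helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         frac = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0) stopf("'%s' must be > 0", name)
  if (nonneg && x < 0) stopf("'%s' must be >= 0", name)
  if (frac && (x < 0 || x > 1)) stopf("'%s' must be in [0, 1]", name)
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be TRUE or FALSE", name)
  invisible(x)
}

## Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
## state afterwards so generators never perturb user-level randomness.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
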