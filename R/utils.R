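# Internal helpers.

# Evaluate `expr` under a given RNG seed, restoring the caller's RNG state
# afterwards so seeded package functions never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic fan-out of one global seed to per-stage seeds (kept < 2^31).
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 7919L + as.integer(offset) * 104729L) %% 2147483647L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

is_prop <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x <= 1

`%||%` <- function(a, b) if (is.null(a)) b else a
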