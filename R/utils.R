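# Internal helpers shared across modules.

# Run `expr` under a local RNG stream so that package internals that need
# randomness (k-means restarts) neither disturb nor depend on the caller's
# random state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x) && x >= 1

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Sample standard deviation that returns 0 (not NA) for length-1 input.
sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)
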