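# Internal helpers shared across modules.

# Cumulative trapezoidal integral of y(t) on a uniform grid.
# volume[1] is 0 by construction.
cumtrapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(dt * (y[-n] + y[-1]) / 2))
}

trapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  sum(dt * (y[-n] + y[-1]) / 2)
}

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_state) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_state) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a reproducible child seed (kept below 2^31) from a parent seed.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483629
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

LPM_PER_LPS <- 60  # L/min per L/s
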