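# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a per-scene seed from a master seed and an index, so cohorts are
# reproducible and order-independent (each scene's stream depends only on
# the master seed and its own index, not on how many scenes came before).
derive_seed <- function(master, index) {
  # affine congruential split; constants are odd primes well below 2^31
  as.integer((as.double(master) * 48271 + as.double(index) * 16807 + 11) %%
    2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# fftfreq in cycles per pixel for an axis of length n
fft_freq <- function(n) {
  k <- 0:(n - 1L)
  ifelse(k <= n %/% 2, k, k - n) / n
}

CHANNELS <- c("R", "G", "B")
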