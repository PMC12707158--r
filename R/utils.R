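# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so simulation functions have no RNG
# side effects.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a per-component substream seed from a base seed, kept inside the
# 32-bit integer range R requires.
seed_stream <- function(seed, stream) {
  as.integer((as.double(seed) %% 1e6) * 2099 + 7919 * stream) %% .Machine$integer.max
}

# Half-up decimal rounding for presentation-layer percentages (base round()
# is half-even; the field convention for printed percentages is half-up).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
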