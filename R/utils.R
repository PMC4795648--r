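# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-identity substream seed; kept below 2^31 - 1.
mix_seed <- function(seed, id) {
  as.integer((as.double(seed) %% 65521) * 32003 + (as.double(id) %% 65521) * 7919) %% 2147483646L + 1L
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# round-half-up to integer (R's round() halves to even)
round_half_up <- function(x) as.integer(floor(x + 0.5))

`%||%` <- function(a, b) if (is.null(a)) b else a
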