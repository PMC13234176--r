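# Internal helpers for seeded determinism.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic child seeds derived from a master seed; kept below 2^31.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + 101 * as.double(stream)) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
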