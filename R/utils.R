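# seed plumbing: every stochastic operation takes an explicit integer seed,
# runs under it, and restores the caller's RNG state afterwards.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic sub-seed derivation, kept below 2^31 (R integers are 32-bit)
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 69069 + 12345 +
                as.double(k) * 1013904223) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
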