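`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.  All stochastic steps in the package
# route through this so that a config seed reproduces runs exactly.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# derive a reproducible child seed (kept within 32-bit integer range)
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 2654435761) %% 2147483647)
}
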