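# Deterministic seed substreams: every stage derives its own 31-bit seed
# from one root seed plus a label, so pipeline stages are reproducible
# independently of each other.
.substream <- function(seed, label) {
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v))
  as.integer((as.numeric(seed) * 1009 + h * 7919) %% 2147483629)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
.with_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483629))
  expr
}
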