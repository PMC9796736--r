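# Small shared helpers.

# Run code with a given RNG seed, restoring the caller's RNG state, so
# simulation p-values are reproducible without clobbering the session RNG.
# seed = NULL uses (and advances) the current RNG state.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic stream derivation: mixes integers (master seed, cell id,
# replicate index, ...) into one seed < 2^31 - 1.  A small LCG-style fold is
# enough here; it only needs to be reproducible and well spread, and keeps
# every intermediate exactly representable in doubles.
mix_seed <- function(...) {
  v <- c(...)
  h <- 104729
  for (x in v) {
    h <- (h * 69069 + (as.numeric(x) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}
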