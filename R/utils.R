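# RNG hygiene: synthesis functions seed a local stream and restore the
# caller's RNG state afterwards, so library code never perturbs a session.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# Coerce a seed to a valid 32-bit integer.
as_seed <- function(seed) {
  s <- as.numeric(seed) %% 2147483647
  as.integer(s)
}

# Derive a reproducible sub-seed for stream i (per subject, per ROI, ...).
derive_seed <- function(seed, i) {
  as.integer((as.numeric(as_seed(seed)) * 48271 + 7919 * as.numeric(i)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
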