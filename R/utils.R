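# Internal helpers shared across modules.

# Round-half-up (round() rounds half to even, which would make counts like
# round(0.5 * N) platform-surprising in split/undersample arithmetic).
.round_half_up <- function(x) as.integer(floor(x + 0.5))

# Scoped RNG: seed the generator, return a restorer for on.exit(), so that
# seeded operations do not disturb the caller's RNG stream.
.local_rng <- function(seed) {
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# Derive stage seeds from one global seed by fixed offsets, kept below 2^31.
.stage_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483629L
}
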