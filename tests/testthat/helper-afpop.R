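# Shared fixtures for the suite.

all_ones <- function() setNames(rep(1, 9), afpop:::MULTIPLIER_NAMES)

# A small desk configuration for unit tests that exercise the strip or the
# plane without needing the full 15-beat protocol.
tiny_config <- function() {
  cfg <- desk_config()
  cfg$strip$ny <- 128L
  cfg$strip$n_beats <- 6
  cfg$strip$n_last <- 2
  cfg
}

# Synthetic profile table with n rows of uniform multipliers (seeded).
synthetic_profiles <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * 9, 0.5, 2), n, 9,
              dimnames = list(NULL, afpop:::MULTIPLIER_NAMES))
  data.frame(profile_id = sprintf("q%03d", seq_len(n)), m)
}
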