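# Internal: derive a component-specific RNG seed from a user-facing seed.
#
# Different pipeline components (cohort simulation, split drawing) must not
# share an RNG stream even when the user passes the same integer seed to
# both -- identical streams would couple, for example, the placement of
# positive labels with the drawn test sets.  Each component therefore seeds
# the RNG with a deterministic hash of (seed, component label).  The hash
# is a plain base-31 string fold modulo the Mersenne prime 2^31 - 1, exact
# in double arithmetic (intermediate values stay far below 2^53).
seed_stream <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}
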