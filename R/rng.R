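# Seed-stream management for the synthetic-data generators.
#
# Each generator draws from its own pseudo-random stream derived from
# (seed, call-site label), so adding a new generator to a simulation run
# never perturbs the fixtures produced by existing ones.

# polynomial rolling hash of a character label, in [0, 2^31 - 2]; exact in
# double arithmetic since intermediate values stay below 2^53
label_hash <- function(label) {
  bytes <- utf8ToInt(label)
  h <- 5381
  for (b in bytes) {
    h <- (h * 127 + b) %% 2147483647
  }
  h
}

# derive the integer seed for one (seed, label) stream
stream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((as.numeric(seed) * 48271 + label_hash(label)) %% 2147483647)
}

# evaluate expr under the stream's RNG state without disturbing the caller's
with_stream <- function(seed, label, expr) {
  withr::with_seed(stream_seed(seed, label), expr)
}
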