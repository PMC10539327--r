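# Deterministic derivation of per-replicate RNG substreams.
#
# A single top-level seed plus a tuple of small integer indices (scenario,
# replicate, regime, stage, ...) maps to a 31-bit seed via a Lehmer-style
# mixing recurrence.  All arithmetic stays below 2^53 so it is exact in
# doubles, and the result is always a valid seed for set.seed().

derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647            # 2^31 - 1
  s <- (abs(as.numeric(seed)) %% m) + 1
  for (i in idx) {
    s <- (s * 48271 + abs(as.numeric(i)) + 1) %% m
    s <- (s * 69621 + 7) %% m
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
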