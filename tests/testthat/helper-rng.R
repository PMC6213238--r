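# Evaluate with a local RNG seed without disturbing the session stream.
with_seed_test <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
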