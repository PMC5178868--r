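# Deterministic fan-out from one root seed to per-stage child seeds.
#
# Every stochastic stage k of a run reseeds with child_seed(root, k), a
# linear-congruential step on the root kept inside the 32-bit signed range
# R's set.seed() accepts. Stages are numbered in a fixed documented order
# (see simulate_trials), so any stage is reproducible in isolation.
child_seed <- function(seed, stage) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer", call. = FALSE)
  as.integer((as.double(seed) %% 2147483647 + 1013904223 * stage) %% 2147483647)
}

with_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}
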