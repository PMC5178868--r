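# Canonical parameter settings used across the suite (the "Fig. 4" regime:
# moderate coupling, equal noise, full-strength stimulus).
canonical_gen <- function() gen_params(1, 1, 0.6, 1)
canonical_so <- function() belief_params("second_order", 1, 1, 0.6)

# Minimal hand-built trial table for metric unit tests.
make_tt <- function(z_post, correct, d = NULL, a = NULL, z_pre = z_post) {
  n <- length(z_post)
  if (is.null(d)) d <- rep(c(-1L, 1L), length.out = n)
  if (is.null(a)) a <- ifelse(correct, d, -d)
  tt <- data.frame(
    trial = seq_len(n), d = d, theta = 1, x_act = a * 1, x_conf = a * 1,
    x_new = NA_real_, a = a, z_pre = z_pre, z_post = z_post,
    correct = correct)
  class(tt) <- c("trial_table", "data.frame")
  tt
}
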