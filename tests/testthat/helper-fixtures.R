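# Shared fixtures built in code: tiny deterministic scorers and a small
# fitted model used across test files.

unit_scale <- function(name = "unit") {
  scale_scorer(name, stats::setNames(rep(1, 20), amylometa:::AA_ALPHABET))
}

# scale with value 0.1 * rank of the residue in alphabet order
ramp_scale <- function(name = "ramp", aggregation = "mean") {
  scale_scorer(name,
               stats::setNames(0.1 * seq_len(20), amylometa:::AA_ALPHABET),
               aggregation = aggregation)
}

random_pssm <- function(seed = 1, name = "rpssm") {
  set.seed(seed)
  m <- matrix(rnorm(120), 6, 20,
              dimnames = list(NULL, amylometa:::AA_ALPHABET))
  pssm_scorer(name, m)
}

random_hex <- function(n, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(amylometa:::AA_ALPHABET, 6, replace = TRUE),
          collapse = "")
  }, "")
}

# small model fitted on synthetic hexapeptides with the built-in scorers
fit_small_model <- function(seed = 42, n_pos = 60, n_neg = 80,
                            separation = 2) {
  d <- gen_labelled_hexapeptides(n_pos = n_pos, n_neg = n_neg,
                                 separation = separation, seed = seed)
  feats <- as.data.frame(compute_features(d))
  feats$label <- d$label
  amylometa(label ~ ., feats)
}
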