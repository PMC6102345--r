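# Shared fixtures, built lazily and cached for the whole test run.
# The full-size network (~53M parameters) and the end-to-end synthetic
# study are expensive, so every test file shares one instance.

.fixtures <- new.env(parent = emptyenv())

get_test_network <- function(seed = 1L) {
  key <- paste0("net", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- build_network(cnn_config(seed = seed))
  }
  .fixtures[[key]]
}

# 6 scenes x 30 s x 20 subjects, full pipeline including the CNN stage.
get_test_study <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- run_synthetic_study(
      n_scenes = 6, duration_s = 30, n_subjects = 20, seed = 1L,
      cnn = TRUE, network = get_test_network(1L))
  }
  .fixtures$study
}

# Band-limited noise the way the correlation analyses see it: white noise
# pushed through the standard conditioning chain.
conditioned_noise <- function(n_in = 1300, rate = 10) {
  condition_series(rnorm(n_in), rate = rate)
}
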