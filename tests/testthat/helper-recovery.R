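# The recovery experiment is the most expensive fixture; compute it once per
# test run and share it across the tests that score it.
recovery_cache <- new.env(parent = emptyenv())

shared_recovery <- function() {
  if (is.null(recovery_cache$rec)) {
    recovery_cache$rec <- recovery_experiment(
      recovery_config(), seed = 1, chains = 2, iter = 800, warmup = 800,
      adapt_delta = 0.9)
  }
  recovery_cache$rec
}
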