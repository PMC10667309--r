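# Small, fast simulator configurations for unit tests. Acceptance tests use
# the full default configuration.

small_config <- function(seed = 11, ...) {
  sim_config(n_hosts = 12, n_phages = 20, seed = seed, ...)
}

quiet_pipeline <- function(...) {
  suppressMessages(suppressWarnings(run_pipeline(...)))
}
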