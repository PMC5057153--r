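# Shared simulated experiments, built once per test run. Sizes are scaled
# down from the default world to keep the suite fast; the acceptance tests
# run the full-size world separately.

.sim_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 42, ...) {
  sim_config(n_genes = 120, gene_length_range = c(600, 1500),
             n_chroms = 2, n_lncrna = 3, seed = seed, ...)
}

small_experiment <- function() {
  if (is.null(.sim_cache$small)) {
    .sim_cache$small <- simulate_experiment(small_config())
  }
  .sim_cache$small
}

# full-scale default-world pipeline, shared by the acceptance criteria
acceptance_pipeline <- function() {
  if (is.null(.sim_cache$acceptance)) {
    .sim_cache$acceptance <- run_pipeline(sim_config(seed = 1))
  }
  .sim_cache$acceptance
}
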