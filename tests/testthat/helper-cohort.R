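# Shared small cohorts, built once per test run.

small_cohort_cfg <- function(seed = 101, ...) {
  sim_config(seed = seed, n_samples = 300, n_genes = 30, n_families = 10,
             expression = list(n_sc_genes = 400, n_cells_per_sample = 15,
                               n_sc_samples = 10),
             ...)
}

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key = "default", maker = NULL) {
  if (is.null(.cohort_cache[[key]])) {
    maker <- maker %||% function() simulate_cohort(small_cohort_cfg())
    .cohort_cache[[key]] <- maker()
  }
  .cohort_cache[[key]]
}
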