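# Shared synthetic cohorts, memoized so expensive default-scale generations
# run once per test session.

.cohort_cache <- new.env(parent = emptyenv())

# Reduced-scale cohort for fast unit tests (same statistical structure).
small_config <- function(seed = 42) {
  simulation_config(seed = seed, n_probes = 4000L, n_genes = 600L)
}

small_cohort <- function(seed = 42) {
  key <- paste0("small", seed)
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, generate_mouse_cohort(small_config(seed)),
           envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

# Default-scale cohort (the study conditions) for recovery checks.
default_cohort <- function(seed) {
  key <- paste0("default", seed)
  if (!exists(key, envir = .cohort_cache)) {
    cfg <- simulation_config(seed = seed)
    assign(key, list(config = cfg, mouse = generate_mouse_cohort(cfg)),
           envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

group_samples <- function(cohort, groups) {
  s <- cohort$sample_sheet
  s$sample_id[s$group %in% groups]
}
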