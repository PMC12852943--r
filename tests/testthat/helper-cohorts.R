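# Shared simulated cohorts for the group-level tests. Built lazily and
# cached for the test run so several test blocks can reuse the same
# study-sized simulations without repeating the cost.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- force(expr)
  .cohort_cache[[key]]
}

# 40 + 40 sham sessions (the model-comparison / regression suite).
sham_correlated <- function() {
  cached("sham_corr", simulate_cohort(40, "correlated", seed = 2024))
}
sham_uncorrelated <- function() {
  cached("sham_unc", simulate_cohort(40, "uncorrelated", seed = 2025))
}

# Per-session latent-state observer traces for the sham suite.
sham_traces <- function(sessions, key) {
  cached(paste0("tr_", key), run_observer(sessions, model = "model2"))
}

# Per-session regression coefficient table for the sham suite.
sham_fits <- function() {
  cached("sham_fits", {
    corr <- sham_correlated()
    unc <- sham_uncorrelated()
    dplyr::bind_rows(
      fit_switch_regressions(corr, traces = sham_traces(corr, "corr")),
      fit_switch_regressions(unc, traces = sham_traces(unc, "unc"))
    )
  })
}

# TUS cohorts: 3 subjects, 8 sham / 6 per target sessions, correlated task.
tus_cohorts <- function() {
  cached("tus", dplyr::bind_rows(
    simulate_cohort(24, "correlated", "sham", n_subjects = 3, seed = 3101),
    simulate_cohort(18, "correlated", "dmpfc", n_subjects = 3, seed = 3102),
    simulate_cohort(18, "correlated", "hippocampus", n_subjects = 3, seed = 3103),
    simulate_cohort(18, "correlated", "thalamus", n_subjects = 3, seed = 3104)
  ))
}

tus_fits <- function() {
  cached("tus_fits", fit_switch_regressions(tus_cohorts()))
}
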