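# Small single-session fixtures for fast unit tests: short correlated
# schedules need an explicit (feasible) reversal count and block length.

small_schedule <- function(n_trials, seed, n_reversals = 1L) {
  gen_correlated_schedule(
    n_trials = n_trials, n_reversals = n_reversals,
    min_block = max(2L, n_trials %/% (2L * (n_reversals + 1L))),
    reversal_lag = 1L, seed = seed
  )
}

small_session <- function(n_trials, seed, ...) {
  simulate_session(small_schedule(n_trials, seed), seed = seed, ...)
}
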