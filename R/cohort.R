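# Cohort-level simulation: many sessions under one condition and policy
# preset, the workhorse behind the group-level analyses.

#' Simulate a cohort of agent sessions
#'
#' Generates `n_sessions` reward schedules of the requested condition and
#' runs the closed-loop agent over each. Session seeds are derived
#' deterministically from `seed`, so a cohort is reproducible from a
#' single integer.
#'
#' @param n_sessions Number of sessions.
#' @param condition `"correlated"` or `"uncorrelated"`.
#' @param preset Policy preset name (see [tus_preset()]) or an
#'   `rb_policy`.
#' @param n_trials Trials per session.
#' @param n_subjects Sessions are assigned round-robin to this many
#'   subject ids.
#' @param model Observer model driving the agents; `NULL` (default) picks
#'   the environment-appropriate observer (model 2 in correlated, model 1
#'   in uncorrelated sessions, matching [condition_policy()]).
#' @param seed Integer seed for the whole cohort.
#' @param session_prefix Prefix for generated session ids.
#' @param ... Passed to the schedule generator.
#' @return A trial-table tibble covering all sessions.
#' @export
simulate_cohort <- function(n_sessions, condition = c("correlated", "uncorrelated"),
                            preset = "sham", n_trials = 170L, n_subjects = 1L,
                            model = NULL, seed = NULL,
                            session_prefix = NULL, ...) {
  condition <- match.arg(condition)
  params <- if (inherits(preset, "rb_policy")) {
    preset
  } else if (preset == "sham") {
    condition_policy(condition)  # environment-adapted intact agent
  } else {
    tus_preset(preset)
  }
  model <- model %||% attr(params, "model") %||% "model2"
  session_prefix <- session_prefix %||%
    paste0(substr(condition, 1, 3), "_", if (is.character(preset)) preset else "custom")
  purrr::map_dfr(seq_len(n_sessions), function(i) {
    s_sched <- derive_seed(seed, i * 3L)
    s_agent <- derive_seed(seed, i * 3L + 1L)
    sched <- if (condition == "correlated") {
      gen_correlated_schedule(n_trials = n_trials, seed = s_sched, ...)
    } else {
      gen_uncorrelated_schedule(n_trials = n_trials, seed = s_sched, ...)
    }
    simulate_session(
      sched, params = params, model = model, seed = s_agent,
      session_id = sprintf("%s_%03d", session_prefix, i),
      subject_id = sprintf("m%d", (i - 1L) %% n_subjects + 1L),
      tus = if (is.character(preset)) preset else "custom"
    )
  })
}
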