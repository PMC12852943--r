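# Running the observer over a behavioural session to produce the
# trial-wise estimate trace used by the behavioural analyses.

# Internal engine shared by run_observer() and simulate_session(): one
# belief per option, updated by outcome on the chosen side and passed
# through the model's transition on both sides every trial.
observer_new <- function(model, grid = NULL) {
  model <- match_model(model)
  grid <- grid %||% grid_for_model(model)
  expected <- if (model == "model2") "reversal_rate" else "drift_sd"
  if (grid$aux_kind != expected) {
    rlang::abort(sprintf("%s requires a %s grid", model, expected))
  }
  list(model = model, grid = grid,
       beliefs = list(L = init_belief(grid), R = init_belief(grid)))
}

# Decision-time readouts per side. The latent-state model reports the MAP
# of the value marginal, the drift model its mean (as in the respective
# analyses); both report the 95% credible width.
observer_side_estimates <- function(obs) {
  est_mode <- if (obs$model == "model2") "map" else "mean"
  out <- list()
  for (side in c("L", "R")) {
    b <- obs$beliefs[[side]]
    out[[paste0("prob_", side)]] <- point_estimates(b, est_mode)
    out[[paste0("mean_", side)]] <- point_estimates(b, "mean")
    out[[paste0("unc_", side)]] <- credible_width(b)
    out[[paste0("rev_", side)]] <-
      if (obs$model == "model2") reversal_probability(b) else NA_real_
  }
  out
}

# Outcome step: Bayes update of the chosen belief (recording the KL update
# signal across it), then the model transition applied to both beliefs to
# form the next trial's priors.
observer_step <- function(obs, choice, outcome) {
  b_pre <- obs$beliefs[[choice]]
  b_post <- bayes_update(b_pre, outcome)
  dkl <- if (obs$model == "model2") {
    kl_update(aux_marginal(b_post), aux_marginal(b_pre))
  } else {
    kl_update(value_marginal(b_post), value_marginal(b_pre))
  }
  obs$beliefs[[choice]] <- b_post
  transition <- if (obs$model == "model2") transition_reversal else transition_drift
  obs$beliefs <- lapply(obs$beliefs, transition)
  list(obs = obs, dkl = dkl)
}

#' Run a Bayesian observer over a session
#'
#' Replays a session's choices and outcomes through the grid-based
#' observer and records, for every trial, the decision-time estimates
#' (computed on the pre-outcome beliefs) and the Kullback-Leibler update
#' signal across the outcome update. Estimates are recorded both per side
#' (`left_*`, `right_*`) and re-keyed by that trial's choice
#' (`chosen_*`/`unchosen_*`).
#'
#' For the latent-state model (`"model2"`) the trace includes the reversal
#' estimate (expected `H` of the chosen option), the reversal EV (expected
#' value of the unchosen option) and `reversal_dkl` (KL over the `H`
#' marginal). For the drift model (`"model1"`) it includes `option_dkl`
#' (KL over the chosen option's value marginal) instead.
#'
#' @param sessions A trial table (tibble) with at least `choice` and
#'   `outcome` columns; multiple sessions are split on `session_id`.
#' @param model `"model1"` or `"model2"`.
#' @param grid Optional [hypothesis_grid()]; defaults to the model's
#'   standard grid.
#' @return A tibble with one row per (session, trial), joinable to the
#'   trial table on `(session_id, trial)`.
#' @export
run_observer <- function(sessions, model = "model2", grid = NULL) {
  model <- match_model(model)
  stopifnot(all(c("choice", "outcome") %in% names(sessions)))
  if (!"session_id" %in% names(sessions)) sessions$session_id <- "s1"
  if (!"trial" %in% names(sessions)) {
    sessions <- dplyr::mutate(sessions, trial = dplyr::row_number(),
                              .by = "session_id")
  }
  if (anyNA(sessions$choice) || anyNA(sessions$outcome)) {
    rlang::abort("sessions contain missing choices or outcomes")
  }
  sessions |>
    dplyr::group_by(.data$session_id) |>
    dplyr::group_modify(function(df, key) {
      observe_one(df$choice, df$outcome, df$trial, model, grid)
    }) |>
    dplyr::ungroup()
}

observe_one <- function(choices, outcomes, trials, model, grid = NULL) {
  n <- length(choices)
  obs <- observer_new(model, grid)
  cols <- c("left_prob", "right_prob", "left_unc", "right_unc", "left_rev",
            "right_rev", "chosen_prob", "unchosen_prob", "chosen_unc",
            "unchosen_unc", "reversal_estimate", "reversal_ev",
            "reversal_dkl", "option_dkl")
  m <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (t in seq_len(n)) {
    est <- observer_side_estimates(obs)
    ch <- choices[t]
    un <- if (ch == "L") "R" else "L"
    stepped <- observer_step(obs, ch, outcomes[t])
    m[t, 1:6] <- c(est$prob_L, est$prob_R, est$unc_L, est$unc_R,
                   est$rev_L, est$rev_R)
    m[t, 7:12] <- c(est[[paste0("prob_", ch)]], est[[paste0("prob_", un)]],
                    est[[paste0("unc_", ch)]], est[[paste0("unc_", un)]],
                    est[[paste0("rev_", ch)]],
                    if (model == "model2") est[[paste0("mean_", un)]] else NA_real_)
    if (model == "model2") m[t, "reversal_dkl"] <- stepped$dkl
    if (model == "model1") m[t, "option_dkl"] <- stepped$dkl
    obs <- stepped$obs
  }
  dplyr::bind_cols(
    tibble::tibble(trial = trials, choice = choices, outcome = outcomes),
    tibble::as_tibble(m),
    tibble::tibble(model = rep(model, n))
  )
}
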