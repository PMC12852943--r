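# Switch/stay choice policies: mapping observer estimates to switch
# probabilities, simulating agents, maximum-likelihood fitting and AIC
# model comparison.
#
# The choice rule is a reconstruction: a Bernoulli-logistic switch/stay
# policy over the same regressor set as the switch regressions (value
# difference, uncertainty difference, reversal estimate). It is the
# minimal policy consistent with those analyses; see the methods vignette.

#' Construct switch-policy parameters
#'
#' The policy sets the log-odds of switching away from the currently held
#' option (the previous trial's choice) as
#' `bias + w_value * value_term + w_unc * (chosen_unc - unchosen_unc) +
#' w_rev * reversal_estimate`, where `value_term` is either the
#' chosen-minus-unchosen probability difference (`"difference"`) or the
#' held option's probability alone (`"chosen"`), and chosen/unchosen refer
#' to the held option and its alternative.
#'
#' @param bias Baseline log-odds of switching.
#' @param w_value Weight on the value term.
#' @param w_unc Weight on the uncertainty difference.
#' @param w_rev Weight on the reversal estimate (latent-state policies
#'   only; must be 0 for model 1 policies).
#' @param value_term `"difference"` or `"chosen"`.
#' @return An `rb_policy` object.
#' @export
policy_params <- function(bias = 0, w_value = 0, w_unc = 0, w_rev = 0,
                          value_term = c("difference", "chosen")) {
  value_term <- match.arg(value_term)
  stopifnot(is.finite(bias), is.finite(w_value), is.finite(w_unc), is.finite(w_rev))
  structure(
    list(bias = bias, w_value = w_value, w_unc = w_unc, w_rev = w_rev,
         value_term = value_term),
    class = "rb_policy"
  )
}

#' @export
print.rb_policy <- function(x, ...) {
  cat(sprintf(
    "<rb_policy> bias=%.3g w_value=%.3g w_unc=%.3g w_rev=%.3g (value term: %s)\n",
    x$bias, x$w_value, x$w_unc, x$w_rev, x$value_term
  ))
  invisible(x)
}

#' Perturbed-policy presets
#'
#' Policy parameter sets emulating intact behaviour (`"sham"`) and the
#' qualitative behavioural signatures seen after focused ultrasound
#' disruption of each node of the reversal circuit: after dmPFC
#' perturbation switching depends only on the held option's recent value;
#' after hippocampus perturbation the reversal estimate loses its
#' influence while uncertainty weighs more; after thalamus perturbation
#' the reversal-estimate influence reverses sign. Magnitudes are
#' calibrated so simulated cohorts reproduce these sign patterns together
#' with realistic switch rates; see the methods vignette.
#'
#' @param target `"sham"`, `"dmpfc"`, `"hippocampus"` or `"thalamus"`.
#' @return An `rb_policy`.
#' @export
tus_preset <- function(target = c("sham", "dmpfc", "hippocampus", "thalamus")) {
  target <- match.arg(target)
  switch(target,
    sham = policy_params(bias = -2.55, w_value = -2.4, w_unc = 2.5, w_rev = 22),
    dmpfc = policy_params(bias = 1, w_value = -4, w_unc = 0, w_rev = 0,
                          value_term = "chosen"),
    hippocampus = policy_params(bias = -0.25, w_value = -2.4, w_unc = 4, w_rev = 0),
    thalamus = policy_params(bias = 1.9, w_value = -2.4, w_unc = 4, w_rev = -22)
  )
}

#' Environment-adapted intact (sham) policy
#'
#' The intact animals adapted their switching strategy to the environment:
#' in the correlated task switching tracked the reversal estimate, while
#' in the uncorrelated task it was driven by the value and uncertainty of
#' the recently chosen option with no latent-state component. The
#' environment-adapted sham agent therefore uses the latent-state
#' (model 2) observer with the reversal-sensitive sham policy in
#' correlated sessions, and the drift (model 1) observer with a
#' value/uncertainty policy (no reversal term) in uncorrelated sessions.
#'
#' @param condition `"correlated"` or `"uncorrelated"`.
#' @return An `rb_policy` with a `"model"` attribute naming the observer
#'   that drives it.
#' @export
condition_policy <- function(condition = c("correlated", "uncorrelated")) {
  condition <- match.arg(condition)
  if (condition == "correlated") {
    p <- tus_preset("sham")
    attr(p, "model") <- "model2"
  } else {
    p <- policy_params(bias = -1.3, w_value = -3.9, w_unc = 5, w_rev = 0)
    attr(p, "model") <- "model1"
  }
  p
}

#' Probability of switching away from the held option
#'
#' @param estimates A named list or one-row data frame with
#'   `chosen_prob`, `unchosen_prob`, `chosen_unc`, `unchosen_unc` and (for
#'   latent-state policies) `reversal_estimate`, all expressed relative to
#'   the held option.
#' @param params An `rb_policy`.
#' @return Probability of switching in \[0, 1\].
#' @export
switch_probability <- function(estimates, params) {
  value_term <- if (params$value_term == "chosen") {
    estimates$chosen_prob
  } else {
    estimates$chosen_prob - estimates$unchosen_prob
  }
  eta <- params$bias + params$w_value * value_term +
    params$w_unc * (estimates$chosen_unc - estimates$unchosen_unc)
  if (params$w_rev != 0) {
    eta <- eta + params$w_rev * estimates$reversal_estimate
  }
  stats::plogis(eta)
}

#' Simulate a closed-loop agent session
#'
#' Runs the observer-plus-policy loop over a reward schedule: on each
#' trial the agent computes decision-time estimates relative to the
#' previously held option, draws switch/stay from the policy, receives a
#' Bernoulli outcome from the schedule, and updates its beliefs. The first
#' trial is an unbiased side choice.
#'
#' @param schedule An `rb_schedule`.
#' @param params An `rb_policy` (e.g. from [tus_preset()]).
#' @param model Observer model driving the agent (`"model2"` default).
#' @param grid Optional [hypothesis_grid()].
#' @param seed Optional integer seed (drives choices, outcomes and timing).
#' @param session_id,subject_id,tus Metadata recorded in the trial table.
#' @return A trial-table tibble with columns `session_id`, `subject_id`,
#'   `condition`, `tus`, `trial`, `p_left`, `p_right`, `choice`,
#'   `outcome`, `iti_s`, `aod_s`.
#' @export
simulate_session <- function(schedule, params = tus_preset("sham"),
                             model = "model2", grid = NULL, seed = NULL,
                             session_id = "s1", subject_id = "m1",
                             tus = "none") {
  model <- match_model(model)
  n <- nrow(schedule)
  timing <- sample_timing(n, seed = derive_seed(seed, 1L))
  with_seed_(derive_seed(seed, 2L), {
    obs <- observer_new(model, grid)
    choices <- character(n)
    outcomes <- integer(n)
    for (t in seq_len(n)) {
      if (t == 1L) {
        choices[t] <- sample(c("L", "R"), 1L)
      } else {
        held <- choices[t - 1L]
        other <- if (held == "L") "R" else "L"
        est <- observer_side_estimates(obs)
        p_sw <- switch_probability(list(
          chosen_prob = est[[paste0("prob_", held)]],
          unchosen_prob = est[[paste0("prob_", other)]],
          chosen_unc = est[[paste0("unc_", held)]],
          unchosen_unc = est[[paste0("unc_", other)]],
          reversal_estimate = est[[paste0("rev_", held)]]
        ), params)
        choices[t] <- if (stats::runif(1) < p_sw) other else held
      }
      p <- if (choices[t] == "L") schedule$p_left[t] else schedule$p_right[t]
      outcomes[t] <- stats::rbinom(1L, 1L, p)
      obs <- observer_step(obs, choices[t], outcomes[t])$obs
    }
    tibble::tibble(
      session_id = session_id,
      subject_id = subject_id,
      condition = attr(schedule, "condition") %||% NA_character_,
      tus = tus,
      trial = seq_len(n),
      p_left = schedule$p_left,
      p_right = schedule$p_right,
      choice = choices,
      outcome = outcomes,
      iti_s = timing$iti_s,
      aod_s = timing$aod_s
    )
  })
}

# Switch/stay design for the policy likelihood: regressors at trial t are
# the decision-time estimates re-keyed by the *previous* trial's choice,
# and the response is whether trial t's choice switched away from it.
policy_design <- function(session, trace) {
  stopifnot(nrow(trace) == nrow(session))
  n <- nrow(trace)
  if (n < 2L) rlang::abort("need at least 2 trials for switch/stay analysis")
  t_idx <- 2:n
  held <- trace$choice[t_idx - 1L]
  pick <- function(l_col, r_col) {
    ifelse(held == "L", trace[[l_col]][t_idx], trace[[r_col]][t_idx])
  }
  tibble::tibble(
    trial = trace$trial[t_idx],
    switch = as.integer(trace$choice[t_idx] != held),
    chosen_prob = pick("left_prob", "right_prob"),
    unchosen_prob = pick("right_prob", "left_prob"),
    chosen_unc = pick("left_unc", "right_unc"),
    unchosen_unc = pick("right_unc", "left_unc"),
    reversal_estimate = pick("left_rev", "right_rev")
  )
}

#' Switch/stay log-likelihood of a session under a policy
#'
#' Sums, over trials 2..n, the Bernoulli log-likelihood of the observed
#' switch/stay event under [switch_probability()] evaluated on the
#' decision-time estimates relative to the previously held option. The
#' first trial has no previous choice and is excluded.
#'
#' @param session A single-session trial table.
#' @param params An `rb_policy`.
#' @param model Observer model supplying the estimates.
#' @param grid Optional grid.
#' @param trace Optional precomputed [run_observer()] trace for this
#'   session and model (avoids recomputation).
#' @return Log-likelihood in nats.
#' @export
session_loglik <- function(session, params, model = "model2", grid = NULL,
                           trace = NULL) {
  trace <- trace %||% run_observer(session, model = model, grid = grid)
  d <- policy_design(session, trace)
  p <- switch_probability(d, params)
  sum(stats::dbinom(d$switch, 1L, p, log = TRUE))
}

neg_loglik_factory <- function(d, with_rev) {
  X <- cbind(1, d$chosen_prob - d$unchosen_prob, d$chosen_unc - d$unchosen_unc)
  if (with_rev) X <- cbind(X, d$reversal_estimate)
  y <- d$switch
  list(
    X = X,
    fn = function(beta) {
      eta <- drop(X %*% beta)
      # numerically stable -sum(y*eta - log(1 + exp(eta)))
      -sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
    },
    gr = function(beta) {
      mu <- stats::plogis(drop(X %*% beta))
      -drop(crossprod(X, y - mu))
    }
  )
}

#' Fit a switch/stay policy by maximum likelihood
#'
#' Multi-start quasi-Newton maximisation of the switch/stay Bernoulli
#' likelihood. Model 2 policies have 4 free parameters (bias, value
#' difference, uncertainty difference, reversal estimate); model 1
#' policies omit the reversal term (3 parameters). Starting points are
#' drawn uniformly from \[-5, 5\] per weight.
#'
#' @param session A single-session trial table (>= 20 trials).
#' @param model `"model1"` or `"model2"` (decides both the observer
#'   supplying regressors and the policy's parameter count).
#' @param grid Optional grid.
#' @param starts Number of random starts (default 10).
#' @param seed Optional seed for the starting points.
#' @param trace Optional precomputed trace.
#' @return An `rb_fit`: fitted `rb_policy`, `loglik`, `k`, `aic`,
#'   `converged`, `session_id`, `n_obs`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_policy <- function(session, model = "model2", grid = NULL, starts = 10L,
                       seed = NULL, trace = NULL) {
  model <- match_model(model)
  if (nrow(session) < 20L) rlang::abort("session must have at least 20 trials")
  if ("session_id" %in% names(session) &&
      length(unique(session$session_id)) > 1L) {
    rlang::abort("fit_policy() takes a single session; see compare_models() for cohorts")
  }
  trace <- trace %||% run_observer(session, model = model, grid = grid)
  d <- policy_design(session, trace)
  with_rev <- model == "model2"
  k <- if (with_rev) 4L else 3L
  obj <- neg_loglik_factory(d, with_rev)
  best <- NULL
  converged <- FALSE
  with_seed_(seed, {
    start_mat <- matrix(stats::runif(starts * k, -5, 5), starts, k)
    start_mat[1, ] <- 0  # always include the null start
    for (s in seq_len(starts)) {
      res <- tryCatch(
        stats::optim(start_mat[s, ], obj$fn, obj$gr, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-10)),
        error = function(e) NULL
      )
      if (is.null(res)) next
      if (is.null(best) || res$value < best$value - 1e-9) best <- res
      if (res$convergence == 0) converged <- TRUE
    }
  })
  if (is.null(best)) {
    rlang::abort("all optimisation starts failed")
  }
  beta <- best$par
  params <- policy_params(
    bias = beta[1], w_value = beta[2], w_unc = beta[3],
    w_rev = if (with_rev) beta[4] else 0
  )
  structure(
    list(
      params = params,
      model = model,
      loglik = -best$value,
      k = k,
      aic = 2 * k + 2 * best$value,
      converged = converged,
      session_id = if ("session_id" %in% names(session)) session$session_id[1] else NA_character_,
      n_obs = nrow(d)
    ),
    class = "rb_fit"
  )
}

#' @export
print.rb_fit <- function(x, ...) {
  cat(sprintf(
    "<rb_fit> %s policy, session %s: loglik %.2f, AIC %.2f (k=%d)%s\n",
    x$model, x$session_id, x$loglik, x$aic, x$k,
    if (x$converged) "" else " [not converged]"
  ))
  print(x$params)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rb_fit <- function(x, ...) {
  p <- x$params
  terms <- c("bias", "w_value", "w_unc", "w_rev")
  est <- c(p$bias, p$w_value, p$w_unc, p$w_rev)
  if (x$model == "model1") {
    terms <- terms[1:3]
    est <- est[1:3]
  }
  tibble::tibble(session_id = x$session_id, model = x$model,
                 term = terms, estimate = est)
}

#' @export
glance.rb_fit <- function(x, ...) {
  tibble::tibble(session_id = x$session_id, model = x$model,
                 loglik = x$loglik, k = x$k, aic = x$aic,
                 converged = x$converged, n_obs = x$n_obs)
}

#' Compare the two observer models on choice data by AIC
#'
#' Fits the model 1 and model 2 switch/stay policies to each session and
#' returns the per-session AIC difference (model 2 minus model 1);
#' negative values favour the latent-state model.
#'
#' @param sessions A trial table; sessions are split on `session_id`.
#' @param grid1,grid2 Optional grids for the two observers.
#' @param starts,seed Passed to [fit_policy()].
#' @return A tibble with one row per session: `aic_model1`, `aic_model2`,
#'   `delta_aic`, convergence flags, and the session's `condition`/`tus`
#'   labels where present.
#' @export
compare_models <- function(sessions, grid1 = NULL, grid2 = NULL,
                           starts = 10L, seed = NULL) {
  if (!"session_id" %in% names(sessions)) sessions$session_id <- "s1"
  ids <- unique(sessions$session_id)
  purrr::map_dfr(seq_along(ids), function(i) {
    ses <- dplyr::filter(sessions, .data$session_id == ids[i])
    f1 <- fit_policy(ses, model = "model1", grid = grid1, starts = starts,
                     seed = derive_seed(seed, i * 2L))
    f2 <- fit_policy(ses, model = "model2", grid = grid2, starts = starts,
                     seed = derive_seed(seed, i * 2L + 1L))
    tibble::tibble(
      session_id = ids[i],
      condition = if ("condition" %in% names(ses)) ses$condition[1] else NA_character_,
      tus = if ("tus" %in% names(ses)) ses$tus[1] else NA_character_,
      aic_model1 = f1$aic,
      aic_model2 = f2$aic,
      delta_aic = f2$aic - f1$aic,
      converged_model1 = f1$converged,
      converged_model2 = f2$converged
    )
  })
}
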