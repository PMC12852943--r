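# Switch/stay policies, simulation, fitting and model comparison.

fake_est <- list(chosen_prob = 0.8, unchosen_prob = 0.3, chosen_unc = 0.4,
                 unchosen_unc = 0.6, reversal_estimate = 0.12)

test_that("switch probability is the logistic of the weighted estimates", {
  expect_equal(switch_probability(fake_est, policy_params(bias = 1.3)),
               plogis(1.3))
  expect_equal(switch_probability(fake_est, policy_params()), 0.5)
  strong <- policy_params(w_value = -60)
  expect_lt(switch_probability(fake_est, strong), 1e-10)
  full <- policy_params(-1, -2, 0.5, 3)
  expect_equal(switch_probability(fake_est, full),
               plogis(-1 - 2 * 0.5 + 0.5 * (-0.2) + 3 * 0.12))
  chosen_only <- policy_params(-1, -2, 0, 0, value_term = "chosen")
  expect_equal(switch_probability(fake_est, chosen_only), plogis(-1 - 1.6))
})

test_that("perturbation presets carry the qualitative sign structure", {
  sham <- tus_preset("sham")
  expect_gt(sham$w_rev, 0)
  expect_lt(sham$w_value, 0)
  expect_lt(tus_preset("thalamus")$w_rev, 0)
  dm <- tus_preset("dmpfc")
  expect_equal(dm$w_unc, 0)
  expect_equal(dm$w_rev, 0)
  expect_equal(dm$value_term, "chosen")
  expect_equal(tus_preset("hippocampus")$w_rev, 0)
  expect_error(tus_preset("ofc"))
})

test_that("a zero-weight policy produces coin-flip switching and seeds give bitwise reproducibility", {
  sch <- gen_correlated_schedule(n_trials = 170, seed = 1)
  flip <- policy_params()
  ses <- lapply(1:12, function(i) simulate_session(sch, flip, seed = i))
  rate <- mean(vapply(ses, function(s) switch_rate(s)$switch_rate, numeric(1)))
  expect_lt(abs(rate - 0.5), 0.03)
  expect_identical(simulate_session(sch, seed = 9),
                   simulate_session(sch, seed = 9))
})

test_that("session log-likelihood matches closed forms and a brute-force recomputation", {
  sch <- small_schedule(60, 3)
  ses <- simulate_session(sch, seed = 3)
  # bias-only null policy: (n-1) * log(1/2)
  expect_equal(session_loglik(ses, policy_params()), 59 * log(0.5))
  # brute-force per-trial recomputation
  params <- tus_preset("sham")
  tr <- run_observer(ses, "model2")
  held <- tr$choice[-nrow(tr)]
  ll <- 0
  for (t in 2:nrow(tr)) {
    h <- held[t - 1]
    o <- if (h == "L") "R" else "L"
    pick <- function(col_l, col_r) if (h == "L") tr[[col_l]][t] else tr[[col_r]][t]
    p_sw <- plogis(params$bias +
      params$w_value * (pick("left_prob", "right_prob") - pick("right_prob", "left_prob")) +
      params$w_unc * (pick("left_unc", "right_unc") - pick("right_unc", "left_unc")) +
      params$w_rev * pick("left_rev", "right_rev"))
    sw <- tr$choice[t] != h
    ll <- ll + log(if (sw) p_sw else 1 - p_sw)
  }
  expect_equal(session_loglik(ses, params, trace = tr), ll, tolerance = 1e-10)
})

test_that("fitting is a maximum-likelihood AIC bookkeeping exercise", {
  sch <- small_schedule(120, 8, 2L)
  ses <- simulate_session(sch, seed = 8)
  tr <- run_observer(ses, "model2")
  fit <- fit_policy(ses, "model2", seed = 1, trace = tr)
  expect_s3_class(fit, "rb_fit")
  expect_equal(fit$aic, 2 * 4 - 2 * fit$loglik)
  expect_equal(fit$k, 4)
  # ML dominance: fitted loglik >= generating-parameter loglik
  expect_gte(fit$loglik,
             session_loglik(ses, tus_preset("sham"), trace = tr) - 1e-6)
  # determinism under an identical seed
  fit2 <- fit_policy(ses, "model2", seed = 1, trace = tr)
  expect_identical(glance(fit), glance(fit2))
  # model 1 policy has three parameters
  f1 <- fit_policy(ses, "model1", seed = 1)
  expect_equal(f1$k, 3)
  expect_equal(nrow(tidy(f1)), 3)
  expect_error(fit_policy(ses[1:10, ]), "at least 20")
})

test_that("the AIC difference reduces to the parameter penalty for equal fits", {
  # a coin-flip agent carries no information about either model's
  # estimates, so both policies fit near the null and dAIC is near +2
  sch <- gen_uncorrelated_schedule(n_trials = 300, change_rate = 0, seed = 2)
  sch$p_left[] <- 0.5
  sch$p_right[] <- 0.5
  ses <- simulate_session(sch, policy_params(), seed = 4)
  cmp <- compare_models(ses, seed = 6)
  expect_equal(cmp$delta_aic, 2, tolerance = 0.5)
})

test_that("pooled parameter recovery returns the generating weights", {
  rec <- recover_parameters(n_sessions = 6, seed = 77)
  expect_setequal(rec$term, c("bias", "w_value", "w_unc", "w_rev"))
  # loose sanity at this reduced size; the acceptance suite runs the
  # full-size recovery
  expect_equal(sign(rec$estimate), sign(rec$true))
  well_identified <- rec$term %in% c("w_value", "w_rev")
  expect_true(all(rec$relative_error[well_identified] < 0.5))
})
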