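# Behavioural statistics: switch-rate bookkeeping, per-session logistic
# regressions, group inference and the two-factor ANOVA.

toy_session <- function(choices, outcomes) {
  tibble::tibble(session_id = "t", trial = seq_along(choices),
                 choice = choices, outcome = outcomes)
}

test_that("consecutive-error bookkeeping matches hand enumeration of toy sequences", {
  # L(0), L(0), R: trial 2 follows one non-reward (stay), trial 3 follows
  # two consecutive non-rewards for the repeated option (switch)
  r <- consecutive_error_switch(toy_session(c("L", "L", "R"), c(0, 0, 1)))
  expect_equal(r$n_obs, c(1L, 1L, 0L))
  expect_equal(r$n_switch, c(0L, 1L, 0L))
  expect_equal(r$switch_rate[1:2], c(0, 1))
  expect_true(is.na(r$switch_rate[3]))
  # an all-rewarded session has no error events at all
  r2 <- consecutive_error_switch(toy_session(rep("L", 6), rep(1, 6)))
  expect_equal(sum(r2$n_obs), 0)
  # a switch resets the run: L(0), R(0), R -> trial 2 counts at run 1,
  # trial 3 counts at run 1 again (run restarted with the new option)
  r3 <- consecutive_error_switch(toy_session(c("L", "R", "R"), c(0, 0, 1)))
  expect_equal(r3$n_obs, c(2L, 0L, 0L))
  expect_equal(r3$n_switch, c(1L, 0L, 0L))
  # nested counts: a survived run of three contributes once at each length
  r4 <- consecutive_error_switch(toy_session(rep("L", 5), c(0, 0, 0, 1, 1)))
  expect_equal(r4$n_obs, c(1L, 1L, 1L))
  expect_equal(r4$n_switch, c(0L, 0L, 0L))
})

test_that("overall switch rate of alternating choices is one", {
  ses <- toy_session(rep(c("L", "R"), 10), rep(1, 20))
  expect_equal(switch_rate(ses)$switch_rate, 1)
})

test_that("switch-rate counts never exceed the number of non-rewarded trials", {
  ses <- small_session(120, 9)
  r <- consecutive_error_switch(ses)
  expect_lte(sum(r$n_obs), sum(ses$outcome == 0))
  expect_true(all(r$switch_rate >= 0 & r$switch_rate <= 1, na.rm = TRUE))
})

test_that("regression designs carry the variant's columns, z-scored within session", {
  ses <- small_session(100, 12)
  tr <- run_observer(ses, "model2")
  d1 <- build_design(tr, "lmem1")
  expect_setequal(setdiff(names(d1), c("trial", "switch")),
                  c("prob_diff", "unc_diff", "rev_est"))
  d2 <- build_design(tr, "lmem2")
  expect_setequal(setdiff(names(d2), c("trial", "switch")),
                  c("chosen_prob", "unchosen_prob", "chosen_unc",
                    "unchosen_unc", "rev_est"))
  for (cl in c("prob_diff", "unc_diff", "rev_est")) {
    expect_equal(mean(d1[[cl]]), 0, tolerance = 1e-12)
    expect_equal(sd(d1[[cl]]), 1, tolerance = 1e-12)
  }
  # without standardization the difference column is the literal difference
  d1r <- build_design(tr, "lmem1", standardize = FALSE)
  held <- tr$choice[-nrow(tr)]
  chosen <- ifelse(held == "L", tr$left_prob[-1], tr$right_prob[-1])
  unchosen <- ifelse(held == "L", tr$right_prob[-1], tr$left_prob[-1])
  expect_equal(d1r$prob_diff, chosen - unchosen)
  # scale factors invert the z-scoring
  sc <- attr(d1, "scales")
  expect_equal(d1$prob_diff * sc$scale[sc$term == "prob_diff"] +
                 sc$center[sc$term == "prob_diff"], d1r$prob_diff)
  expect_error(build_design(tr[1:8, ], "lmem1"), "10")
  expect_error(build_design(run_observer(ses, "model1"), "lmem1"), "model 2")
})

test_that("hand-rolled IRLS agrees with the glm oracle and is monotone in likelihood", {
  set.seed(31)
  n <- 400
  d <- tibble::tibble(
    x1 = rnorm(n), x2 = rnorm(n),
    switch = rbinom(n, 1, plogis(-0.5 + 0.8 * x1 - 1.2 * x2))
  )
  fit <- logistic_irls(d)
  orc <- glm(switch ~ x1 + x2, family = binomial, data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(orc)), tolerance = 1e-6)
  expect_equal(fit$coefficients$std_error,
               unname(summary(orc)$coefficients[, 2]), tolerance = 1e-4)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_path) > -1e-8))
})

test_that("IRLS recovers a known logistic truth at large n and handles null data", {
  set.seed(32)
  n <- 5000
  d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  d$switch <- rbinom(n, 1, plogis(0.4 - 0.9 * d$x1 + 0.6 * d$x2))
  fit <- logistic_irls(d)
  expect_equal(fit$coefficients$estimate, c(0.4, -0.9, 0.6), tolerance = 0.1)
  # response independent of the regressors: slopes ~ 0, intercept ~ logit(mean)
  d0 <- tibble::tibble(x1 = rnorm(500), switch = rep(c(0, 1, 0, 0), 125))
  f0 <- logistic_irls(d0)
  expect_equal(f0$coefficients$estimate[1], qlogis(0.25), tolerance = 0.3)
  expect_lt(abs(f0$coefficients$estimate[2]), 0.3)
})

test_that("perfect separation is flagged rather than thrown", {
  d <- tibble::tibble(x1 = c(rep(-1, 20), rep(1, 20)),
                      switch = c(rep(0, 20), rep(1, 20)))
  fit <- logistic_irls(d)
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("group contrasts degenerate correctly when all sessions agree", {
  fits <- tidyr::expand_grid(session_id = sprintf("s%d", 1:8),
                             term = c("intercept", "rev_est")) |>
    dplyr::mutate(estimate = 0.7,
                  condition = rep(c("a", "b"), each = 8))
  suppressWarnings(gc <- group_contrast(fits, "condition"))
  rev_row <- gc$contrast[gc$contrast$term == "rev_est", ]
  expect_equal(rev_row$diff, 0)
  expect_equal(rev_row$mw_p, 1)
  expect_error(group_contrast(fits[fits$session_id %in% c("s1", "s2"), ], "condition"),
               "3 sessions")
})

test_that("the two-factor ANOVA matches a direct aov oracle and its degenerate cases", {
  # identical rates everywhere: interaction reported as F = 0, p = 1
  flat <- tidyr::expand_grid(session_id = sprintf("s%d", 1:6),
                             condition = c("x", "y"), run_length = 1:3) |>
    dplyr::mutate(switch_rate = 0.4)
  out <- anova_session_by_errors(flat)
  ia <- attr(out, "interaction")
  expect_equal(ia$statistic, 0)
  expect_equal(ia$p_value, 1)
  # pure main effect of run length: interaction F ~ 0 against the aov oracle
  set.seed(41)
  main <- tidyr::expand_grid(session_id = sprintf("s%d", 1:10),
                             condition = c("x", "y"), run_length = 1:3) |>
    dplyr::mutate(switch_rate = 0.2 + 0.1 * run_length + rnorm(60, 0, 0.03))
  out2 <- anova_session_by_errors(main)
  orc <- summary(aov(switch_rate ~ condition * factor(run_length), data = main))[[1]]
  expect_equal(attr(out2, "interaction")$statistic, orc$`F value`[3], tolerance = 1e-10)
  expect_equal(attr(out2, "interaction")$p_value, orc$`Pr(>F)`[3], tolerance = 1e-10)
  expect_gt(attr(out2, "interaction")$p_value, 0.05)
  # empty cells are an explicit error
  expect_error(anova_session_by_errors(dplyr::filter(main, !(condition == "x" & run_length == 2))),
               "empty")
})
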