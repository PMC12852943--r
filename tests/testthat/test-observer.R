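# Grid-based belief operations: analytic values, transitions, estimates.

g2 <- hypothesis_grid("reversal_rate")
g1 <- hypothesis_grid("drift_sd")

test_that("the uniform initial belief has the textbook summary statistics", {
  b <- init_belief(g2)
  expect_equal(sum(b$pmf), 1, tolerance = 1e-12)
  expect_true(all(abs(b$pmf - 1 / 3131) < 1e-15))
  expect_equal(reversal_probability(b), 0.15, tolerance = 1e-9)
  expect_equal(point_estimates(b, "mean"), 0.5, tolerance = 1e-9)
  expect_equal(credible_width(b), 0.95, tolerance = 1e-9)
})

test_that("outcome likelihood reads v or 1 - v and is complementary", {
  w1 <- outcome_likelihood(g2, 1)
  w0 <- outcome_likelihood(g2, 0)
  expect_equal(w1[g2$v == 0.37], 0.37)
  expect_equal(w0[g2$v == 0.37], 0.63)
  expect_equal(w1 + w0, rep(1, length(g2$v)))
  expect_error(outcome_likelihood(g2, 2), "0 or 1")
})

test_that("a single outcome from the uniform prior gives the discrete Beta(2,1) posterior", {
  post1 <- bayes_update(init_belief(g2), 1)
  # E[v] = sum(v^2)/sum(v) on the 101-point grid = 33.835/50.5
  expect_equal(point_estimates(post1, "mean"), 33.835 / 50.5, tolerance = 1e-9)
  expect_equal(point_estimates(post1, "map"), 1)
  post0 <- bayes_update(init_belief(g2), 0)
  expect_equal(point_estimates(post0, "mean"), 1 - 33.835 / 50.5, tolerance = 1e-9)
  expect_equal(point_estimates(post0, "map"), 0)
  # width vs the analytic Beta(2,1) quantiles sqrt(0.025), sqrt(0.975)
  expect_equal(credible_width(post1), sqrt(0.975) - sqrt(0.025), tolerance = 0.02)
})

test_that("the reversal transition is the per-slice uniform-leak mixture", {
  # point mass at v = 1, H = 0.3: prior(v=1) = 0.7 + 0.3/101
  pm <- matrix(0, 101, 31)
  pm[101, 31] <- 1
  b <- revbandit:::new_belief(g2, pm)
  tr <- transition_reversal(b)
  expect_equal(tr$pmf[101, 31], 0.7 + 0.3 / 101, tolerance = 1e-9)
  expect_equal(sum(tr$pmf), 1, tolerance = 1e-12)
  # H mass at 0 leaks nothing
  pm0 <- matrix(0, 101, 31)
  pm0[55, 1] <- 1
  tr0 <- transition_reversal(revbandit:::new_belief(g2, pm0))
  expect_equal(tr0$pmf, pm0, tolerance = 1e-12)
  # the uniform joint is a fixed point
  u <- init_belief(g2)
  expect_equal(transition_reversal(u)$pmf, u$pmf, tolerance = 1e-12)
})

test_that("the drift transition convolves per slice, keeps mass and spreads entropy", {
  # sigma = 0 slice is the identity
  pm <- matrix(0, 101, 31)
  pm[51, 1] <- 1
  tr <- transition_drift(revbandit:::new_belief(g1, pm))
  expect_equal(tr$pmf, pm, tolerance = 1e-12)
  # point mass at v = 0.5 under sigma = 0.05: symmetric bump, mass 1, mean 0.5
  j <- which(abs(g1$aux - 0.05) < 1e-9)
  pm2 <- matrix(0, 101, 31)
  pm2[51, j] <- 1
  tr2 <- transition_drift(revbandit:::new_belief(g1, pm2))
  expect_equal(sum(tr2$pmf), 1, tolerance = 1e-12)
  marg <- tr2$pmf[, j]
  expect_equal(sum(g1$v * marg) / sum(marg), 0.5, tolerance = 1e-9)
  expect_equal(marg, rev(marg), tolerance = 1e-12)
  # repeated application never decreases value-marginal entropy
  b <- bayes_update(bayes_update(init_belief(g1), 1), 1)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  last <- ent(value_marginal(b))
  for (i in 1:50) {
    b <- transition_drift(b)
    e <- ent(value_marginal(b))
    expect_gte(e, last - 1e-12)
    last <- e
  }
})

test_that("credible width of a point mass is within one grid step of zero", {
  pm <- matrix(0, 101, 31)
  pm[40, 3] <- 1
  expect_lte(credible_width(revbandit:::new_belief(g2, pm)), 0.01)
})

test_that("reversal probability and reversal EV are the stated expectations", {
  pm <- matrix(0, 101, 31)
  pm[, 11] <- 1 / 101  # H point mass at 0.1
  b <- revbandit:::new_belief(g2, pm)
  expect_equal(reversal_probability(b), 0.1, tolerance = 1e-9)
  expect_error(reversal_probability(init_belief(g1)), "model 2")
  pm2 <- matrix(0, 101, 31)
  pm2[81, 5] <- 1  # value point mass at 0.8
  expect_equal(reversal_ev(revbandit:::new_belief(g2, pm2)), 0.8, tolerance = 1e-9)
  expect_equal(reversal_ev(init_belief(g2)), 0.5, tolerance = 1e-9)
  set.seed(4)
  p <- runif(101); p <- p / sum(p)
  pm3 <- outer(p, rep(1 / 31, 31))
  expect_equal(reversal_ev(revbandit:::new_belief(g2, pm3)),
               sum(g2$v * p), tolerance = 1e-12)
})

test_that("the KL update signal matches hand-computed values and Gibbs' inequality", {
  expect_equal(kl_update(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_update(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_error(kl_update(c(0.5, 0.5), c(1, 0)), "KL")
  set.seed(9)
  for (i in 1:20) {
    q <- runif(31); q <- q / sum(q)
    p <- runif(31); p <- p / sum(p)
    expect_gte(kl_update(p, q), 0)
  }
})

test_that("mass is conserved through long random update/transition chains", {
  set.seed(2)
  for (kind in c("reversal_rate", "drift_sd")) {
    b <- init_belief(hypothesis_grid(kind))
    transition <- if (kind == "reversal_rate") transition_reversal else transition_drift
    for (t in 1:30) {
      b <- transition(bayes_update(b, rbinom(1, 1, 0.6)))
      expect_lt(abs(sum(b$pmf) - 1), 1e-10)
      expect_true(all(b$pmf >= 0))
    }
  }
})

test_that("clamping H to zero reduces the latent-state model to Beta-binomial accumulation", {
  # grid with only H = 0: the transition is the identity, so the belief is
  # the discretized Beta posterior of the outcome counts
  g0 <- hypothesis_grid("reversal_rate", n_aux = 2, aux_max = 1e-9)
  b <- init_belief(g0)
  x <- c(1, 1, 0, 1, 0, 1, 1)
  for (xi in x) b <- transition_reversal(bayes_update(b, xi))
  a <- sum(x) + 1
  bb <- sum(1 - x) + 1
  expected <- dbeta(g0$v, a, bb)
  expected <- expected / sum(expected)
  expect_lt(max(abs(value_marginal(b) - expected)), 1e-8)
})
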