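# Core belief operations: likelihood, Bayes update, transition functions,
# and the point estimates read out of a belief.

#' Outcome likelihood over the value grid
#'
#' The likelihood of a binary outcome given each value hypothesis: `v` for
#' a reward, `1 - v` for a non-reward. The auxiliary dimension does not
#' enter the likelihood.
#'
#' @param grid An [hypothesis_grid()].
#' @param x Outcome, 0 (no reward) or 1 (reward).
#' @return Numeric vector of likelihood weights, one per value grid point.
#' @export
outcome_likelihood <- function(grid, x) {
  if (!(length(x) == 1L && x %in% c(0, 1))) {
    rlang::abort("outcome must be a single 0 or 1")
  }
  if (x == 1) grid$v else 1 - grid$v
}

#' Bayesian update of a belief with one outcome
#'
#' Multiplies every cell of the joint pmf by the outcome likelihood of its
#' value coordinate, then renormalizes the joint to total mass 1.
#'
#' @param belief An `rb_belief`.
#' @param x Outcome, 0 or 1.
#' @return The posterior `rb_belief`.
#' @examples
#' b <- init_belief(hypothesis_grid("reversal_rate"))
#' post <- bayes_update(b, 1)
#' sum(hypothesis_grid("reversal_rate")$v * value_marginal(post))  # ~0.670
#' @export
bayes_update <- function(belief, x) {
  lik <- outcome_likelihood(belief$grid, x)
  new_belief(belief$grid, normalize_pmf(belief$pmf * lik))
}

#' Reversal (uniform-leak) transition for the latent-state model
#'
#' Carries the posterior on trial `t` into the prior for trial `t + 1`.
#' Within each reversal-rate slice `H = j`, the value distribution becomes a
#' mixture: with weight `1 - j` the previous posterior, with weight `j` a
#' uniform distribution over the value grid. The joint is then renormalized.
#' A uniform joint is a fixed point, and an `H` slice at 0 leaks nothing.
#'
#' @param belief An `rb_belief` on a `reversal_rate` grid.
#' @return The transitioned `rb_belief`.
#' @export
transition_reversal <- function(belief) {
  if (belief$grid$aux_kind != "reversal_rate") {
    rlang::abort("transition_reversal() requires a reversal_rate grid")
  }
  h <- belief$grid$aux
  n_v <- length(belief$grid$v)
  p_h <- colSums(belief$pmf)
  # per slice: (1 - j) * joint(v, j) + j * (1/n_v) * p(H = j)
  pmf <- sweep(belief$pmf, 2, 1 - h, `*`) +
    matrix(h * p_h / n_v, n_v, length(h), byrow = TRUE)
  new_belief(belief$grid, normalize_pmf(pmf))
}

#' Gaussian-drift transition for the drift model
#'
#' Within each drift slice `sigma`, the value distribution is convolved
#' with a discrete Gaussian kernel of standard deviation `sigma`, truncated
#' at the \[0, 1\] boundary and renormalized per slice (so no mass escapes
#' the support); the joint is then renormalized. The `sigma = 0` slice is
#' the identity.
#'
#' @param belief An `rb_belief` on a `drift_sd` grid.
#' @return The transitioned `rb_belief`.
#' @export
transition_drift <- function(belief) {
  if (belief$grid$aux_kind != "drift_sd") {
    rlang::abort("transition_drift() requires a drift_sd grid")
  }
  kernels <- drift_kernels(belief$grid)
  pmf <- belief$pmf
  for (k in seq_along(kernels)) {
    pmf[, k] <- kernels[[k]] %*% belief$pmf[, k]
  }
  new_belief(belief$grid, normalize_pmf(pmf))
}

# Column-stochastic convolution matrices, one per sigma slice; cached per
# grid geometry since they are reused every trial.
drift_kernels <- local({
  cache <- new.env(parent = emptyenv())
  function(grid) {
    key <- paste0(length(grid$v), "_", paste0(signif(range(grid$aux), 10), collapse = "_"),
                  "_", length(grid$aux))
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- grid$v
    kernels <- lapply(grid$aux, function(sigma) {
      if (sigma <= 0) return(diag(length(v)))
      k <- outer(v, v, function(a, b) stats::dnorm(a - b, sd = sigma))
      sweep(k, 2, colSums(k), `/`)  # truncate at [0,1] and renormalize
    })
    cache[[key]] <- kernels
    kernels
  }
})

#' Point estimate of the value marginal
#'
#' @param belief An `rb_belief`.
#' @param mode `"map"` — grid value with the largest marginal mass (ties
#'   broken toward the smallest value) — or `"mean"` — the expected value.
#' @return A probability in \[0, 1\].
#' @export
point_estimates <- function(belief, mode = c("map", "mean")) {
  mode <- match.arg(mode)
  pv <- value_marginal(belief)
  if (mode == "map") {
    belief$grid$v[which.max(pv)]
  } else {
    sum(belief$grid$v * pv)
  }
}

#' 95% credible width of the value marginal
#'
#' The distance between the 2.5th and 97.5th centiles of the value
#' marginal. Quantiles are obtained by linear interpolation of the
#' cumulative mass, with each grid point's mass located at the point and
#' plotting positions scaled so the first and last grid points map to
#' cumulative 0 and 1 (the weighted analogue of the usual type-7 sample
#' quantile). A uniform marginal therefore has width exactly 0.95.
#'
#' @param belief An `rb_belief`.
#' @return Width in \[0, 1\].
#' @export
credible_width <- function(belief) {
  pv <- value_marginal(belief)
  q <- marginal_quantile(belief$grid$v, pv, c(0.025, 0.975))
  q[2] - q[1]
}

# Weighted type-7-style quantiles of a discrete marginal. Zero-mass grid
# points are dropped; each remaining atom i sits at plotting position
# (mass strictly before i) / (1 - mass of the last atom), so the first and
# last atoms map to 0 and 1 and equal masses reduce to type-7 positions.
marginal_quantile <- function(v, p, probs) {
  keep <- p > 0
  v <- v[keep]
  p <- p[keep] / sum(p[keep])
  n <- length(p)
  if (n == 1L) return(rep(v, length(probs)))
  cs <- cumsum(p)
  u <- (cs - p) / (1 - p[n])
  stats::approx(u, v, xout = probs, rule = 2, ties = "ordered")$y
}

#' Expected reversal rate of a latent-state belief
#'
#' The reversal estimate: the expected value of `H` under the current
#' belief, marginalising over value hypotheses.
#'
#' @param belief An `rb_belief` on a `reversal_rate` grid.
#' @return Expected `H` in \[0, 0.3\].
#' @export
reversal_probability <- function(belief) {
  if (belief$grid$aux_kind != "reversal_rate") {
    rlang::abort("reversal_probability() requires a reversal_rate (model 2) belief")
  }
  sum(belief$grid$aux * colSums(belief$pmf))
}

#' Expected value of switching (reversal EV)
#'
#' The expected reward probability of the currently unchosen option under
#' its value marginal: what a switch would be worth.
#'
#' @param unchosen_belief The unchosen option's `rb_belief`.
#' @return Expected value in \[0, 1\].
#' @export
reversal_ev <- function(unchosen_belief) {
  sum(unchosen_belief$grid$v * value_marginal(unchosen_belief))
}

#' Kullback-Leibler divergence between two marginals
#'
#' `sum(post * log(post / prior))` in nats, with `0 * log(0 / q) = 0`.
#' Used as the trial-wise belief-update signal: over the `H` marginal for
#' the latent-state model, over an option's value marginal for the drift
#' model.
#'
#' @param posterior,prior Normalized mass vectors on the same grid.
#' @return Nonnegative divergence in nats.
#' @export
kl_update <- function(posterior, prior) {
  stopifnot(length(posterior) == length(prior))
  nz <- posterior > 0
  if (any(nz & prior <= 0)) {
    rlang::abort("posterior has mass where the prior has none; KL undefined")
  }
  sum(posterior[nz] * log(posterior[nz] / prior[nz]))
}
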