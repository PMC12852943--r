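# Reward-schedule generators for the two task environments, trial timing,
# and stochastic reward delivery.

# Default schedule-decorrelation settings, calibrated once by simulation
# so that, at the default levels 0.9/0.05 and 1-7 reversals per 170-trial
# session, the population mean Pearson correlation between the two
# options' probability series is close to -0.8 while every schedule
# remains negatively correlated; see the methods vignette.
# DEFAULT_LEVEL_JITTER: SD of the Gaussian perturbation applied to each
# block's reward-probability level (clipped to [0,1]).
# DEFAULT_REVERSAL_LAG: the two options do not reverse on exactly the
# same trial; each option's change point trails the latent-state switch
# by an independent uniform lag on {0, ..., lag} trials.
DEFAULT_LEVEL_JITTER <- 0.08
DEFAULT_REVERSAL_LAG <- 11L

#' Generate a correlated (two latent states) reversal schedule
#'
#' The correlated environment has two anti-phased latent states: in one the
#' left option's reward probability is high and the right option's low, in
#' the other the assignment is reversed. The state reverses at 1-7 randomly
#' placed trials per session, with every block at least `min_block` trials
#' long (reversal placement is uniform over all feasible positions, i.e.
#' independent of behaviour). Two sources of decorrelation keep the two
#' series from being exactly anti-phased, as in the real schedules: each
#' block's high and low levels carry independent Gaussian jitter (clipped
#' to \[0, 1\]), and at each latent-state switch the two options change
#' level after independent uniform lags of 0 to `reversal_lag` trials. At
#' default settings the population mean Pearson r is close to -0.8 and
#' every schedule remains negatively correlated.
#'
#' @param n_trials Trials per session (default 170).
#' @param n_reversals Number of latent-state reversals; `NULL` (default)
#'   samples uniformly from 1-7.
#' @param level_high,level_low Base reward-probability levels.
#' @param level_jitter SD of the per-block Gaussian level jitter.
#' @param reversal_lag Maximum per-option lag (trials) between the latent
#'   switch and that option's level change.
#' @param min_block Minimum trials between reversals (and before the first
#'   and after the last).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return An `rb_schedule` tibble with columns `trial`, `p_left`,
#'   `p_right`, `reversal` (TRUE on trials where the latent state switches)
#'   and attributes `condition` and `reversal_trials`.
#' @examples
#' sch <- gen_correlated_schedule(seed = 1)
#' cor(sch$p_left, sch$p_right)  # strongly negative
#' @export
gen_correlated_schedule <- function(n_trials = 170L, n_reversals = NULL,
                                    level_high = 0.9, level_low = 0.05,
                                    level_jitter = DEFAULT_LEVEL_JITTER,
                                    reversal_lag = DEFAULT_REVERSAL_LAG,
                                    min_block = 15L, seed = NULL) {
  stopifnot(n_trials >= 2, level_low >= 0, level_high <= 1,
            level_low < level_high, level_jitter >= 0, reversal_lag >= 0,
            min_block >= 1, reversal_lag < min_block)
  with_seed_(seed, {
    k <- n_reversals %||% sample.int(7L, 1L)
    if (n_trials < (k + 1L) * min_block) {
      rlang::abort(sprintf(
        "infeasible block constraint: %d reversals with min_block %d need at least %d trials (have %d)",
        k, min_block, (k + 1L) * min_block, n_trials
      ))
    }
    lens <- block_lengths(n_trials, k, min_block)
    rev_trials <- cumsum(lens)[seq_len(k)] + 1L
    state0 <- sample(c(0L, 1L), 1L)  # which option starts high
    one_option <- function(is_left) {
      # level change points: the latent reversals, each delayed by an
      # independent lag for this option (capped at the session end)
      changes <- rev_trials + sample.int(reversal_lag + 1L, k, replace = TRUE) - 1L
      changes <- changes[changes <= n_trials]
      left_high <- state0 == 0L
      high_now <- if (is_left) left_high else !left_high
      p <- numeric(n_trials)
      bounds <- c(1L, changes, n_trials + 1L)
      for (b in seq_len(length(bounds) - 1L)) {
        lvl <- clip01(stats::rnorm(
          1, if (high_now) level_high else level_low, level_jitter))
        p[bounds[b]:(bounds[b + 1L] - 1L)] <- lvl
        high_now <- !high_now
      }
      p
    }
    p_left <- one_option(TRUE)
    p_right <- one_option(FALSE)
    new_schedule(p_left, p_right, rev_trials, "correlated")
  })
}

#' Generate an uncorrelated reversal schedule
#'
#' Each option independently alternates between a high and a low reward
#' level: on every trial (after the first) each option's level toggles with
#' probability `change_rate`, and the level of each new segment is drawn
#' with the same Gaussian jitter as in the correlated generator. Because
#' the two options change independently, the expected Pearson correlation
#' between the two probability series is 0. As a design criterion (the
#' analogue of an experimenter constructing genuinely uncorrelated
#' schedules), candidate schedule pairs whose realized |r| exceeds
#' `max_abs_r` are redrawn, so individual sessions are reliably
#' near-uncorrelated, not just uncorrelated on average.
#'
#' @inheritParams gen_correlated_schedule
#' @param change_rate Per-trial probability that an option's level toggles.
#' @param trial_jitter SD of optional additional per-trial Gaussian
#'   probability jitter (default 0: stepwise schedules).
#' @param max_abs_r Design criterion: largest acceptable |Pearson r|
#'   between the two generated series (set to 1 to disable redrawing).
#' @return An `rb_schedule` tibble; `reversal` marks trials where either
#'   option's level changed.
#' @export
gen_uncorrelated_schedule <- function(n_trials = 170L, change_rate = 0.02,
                                      level_high = 0.9, level_low = 0.05,
                                      level_jitter = DEFAULT_LEVEL_JITTER,
                                      trial_jitter = 0,
                                      max_abs_r = 0.2, seed = NULL) {
  stopifnot(n_trials >= 2, change_rate >= 0, change_rate < 1,
            level_low >= 0, level_high <= 1, level_low < level_high,
            level_jitter >= 0, trial_jitter >= 0, max_abs_r > 0)
  with_seed_(seed, {
    one_option <- function() {
      high <- sample(c(TRUE, FALSE), 1L)
      lvl <- clip01(stats::rnorm(1, if (high) level_high else level_low, level_jitter))
      p <- numeric(n_trials)
      p[1] <- lvl
      changes <- integer(0)
      for (t in 2:n_trials) {
        if (stats::runif(1) < change_rate) {
          high <- !high
          lvl <- clip01(stats::rnorm(1, if (high) level_high else level_low, level_jitter))
          changes <- c(changes, t)
        }
        p[t] <- lvl
      }
      if (trial_jitter > 0) p <- clip01(p + stats::rnorm(n_trials, 0, trial_jitter))
      list(p = p, changes = changes)
    }
    for (try in 1:200) {
      l <- one_option()
      r <- one_option()
      rho <- suppressWarnings(stats::cor(l$p, r$p))
      # both options must actually change, and the realized correlation
      # must be near zero (redraw otherwise)
      ok <- length(l$changes) > 0 && length(r$changes) > 0 &&
        (change_rate == 0 || (is.finite(rho) && abs(rho) <= max_abs_r))
      if (ok || change_rate == 0) break
      if (try == 200L) {
        rlang::abort("could not draw an uncorrelated schedule meeting max_abs_r in 200 tries")
      }
    }
    new_schedule(l$p, r$p, sort(unique(c(l$changes, r$changes))), "uncorrelated")
  })
}

new_schedule <- function(p_left, p_right, reversal_trials, condition) {
  n <- length(p_left)
  out <- tibble::tibble(
    trial = seq_len(n),
    p_left = p_left,
    p_right = p_right,
    reversal = seq_len(n) %in% reversal_trials
  )
  structure(out,
            condition = condition,
            reversal_trials = as.integer(reversal_trials),
            class = c("rb_schedule", class(out)))
}

# Uniformly sample k+1 block lengths >= min_block summing to n (uniform
# over weak compositions of the slack, via the stars-and-bars bijection).
block_lengths <- function(n, k, min_block) {
  slack <- n - (k + 1L) * min_block
  if (k == 0L) return(n)
  y <- sort(sample.int(slack + k, k))
  parts <- diff(c(0L, y, slack + k + 1L)) - 1L
  parts + min_block
}

#' Sample trial timing
#'
#' Inter-trial intervals are uniform on \[6.5, 7.5\] s. Action-outcome
#' delays are drawn from a scaled Beta distribution on \[0.103, 8.770\] s
#' whose shape parameters are solved by moment matching so the population
#' mean is 3.394 s and the population variance 0.605 s^2 (alpha ~ 10.72,
#' beta ~ 17.52).
#'
#' @param n_trials Number of trials.
#' @param seed Optional integer seed.
#' @return A tibble with columns `iti_s` and `aod_s`.
#' @export
sample_timing <- function(n_trials, seed = NULL) {
  stopifnot(n_trials >= 1)
  sh <- aod_beta_shapes()
  with_seed_(seed, tibble::tibble(
    iti_s = stats::runif(n_trials, 6.5, 7.5),
    aod_s = AOD_MIN + (AOD_MAX - AOD_MIN) *
      stats::rbeta(n_trials, sh$alpha, sh$beta)
  ))
}

AOD_MIN <- 0.103
AOD_MAX <- 8.770
AOD_MEAN <- 3.394
AOD_VAR <- 0.605

# Beta shape parameters matching the target delay mean and variance after
# rescaling to [AOD_MIN, AOD_MAX].
aod_beta_shapes <- function() {
  range <- AOD_MAX - AOD_MIN
  mu <- (AOD_MEAN - AOD_MIN) / range
  v <- AOD_VAR / range^2
  s <- mu * (1 - mu) / v - 1
  list(alpha = mu * s, beta = (1 - mu) * s)
}

#' Deliver a stochastic reward outcome
#'
#' Bernoulli draw with the chosen option's scheduled reward probability on
#' the given trial.
#'
#' @param schedule An `rb_schedule`.
#' @param trial Trial index.
#' @param choice `"L"` or `"R"`.
#' @param seed Optional integer seed.
#' @return 0 or 1.
#' @export
deliver_outcome <- function(schedule, trial, choice, seed = NULL) {
  stopifnot(trial >= 1, trial <= nrow(schedule))
  if (!(length(choice) == 1L && choice %in% c("L", "R"))) {
    rlang::abort("choice must be \"L\" or \"R\"")
  }
  p <- if (choice == "L") schedule$p_left[trial] else schedule$p_right[trial]
  with_seed_(seed, stats::rbinom(1L, 1L, p))
}
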