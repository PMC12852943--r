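# Independent brute-force observer: direct nested-loop evaluation of the
# outcome update and the two transition rules on an explicit grid. Kept
# deliberately naive (element loops, no shared code with the package) so
# it can serve as an oracle for the vectorised implementation.

oracle_grid <- function(n_v = 11, n_aux = 4, aux_max = 0.3) {
  list(v = seq(0, 1, length.out = n_v),
       aux = seq(0, aux_max, length.out = n_aux))
}

oracle_uniform <- function(g) {
  matrix(1 / (length(g$v) * length(g$aux)), length(g$v), length(g$aux))
}

oracle_update <- function(g, pmf, x) {
  out <- pmf
  for (i in seq_along(g$v)) {
    lik <- if (x == 1) g$v[i] else 1 - g$v[i]
    for (j in seq_along(g$aux)) out[i, j] <- lik * pmf[i, j]
  }
  out / sum(out)
}

oracle_transition_reversal <- function(g, pmf) {
  out <- pmf
  n_v <- length(g$v)
  for (j in seq_along(g$aux)) {
    h <- g$aux[j]
    p_h <- 0
    for (i in seq_len(n_v)) p_h <- p_h + pmf[i, j]
    for (i in seq_len(n_v)) {
      out[i, j] <- (1 - h) * pmf[i, j] + h * (1 / n_v) * p_h
    }
  }
  out / sum(out)
}

oracle_transition_drift <- function(g, pmf) {
  out <- pmf
  n_v <- length(g$v)
  for (j in seq_along(g$aux)) {
    s <- g$aux[j]
    if (s <= 0) next
    k <- matrix(0, n_v, n_v)
    for (a in seq_len(n_v)) {
      for (b in seq_len(n_v)) k[a, b] <- stats::dnorm(g$v[a] - g$v[b], sd = s)
    }
    for (b in seq_len(n_v)) {
      tot <- sum(k[, b])
      for (a in seq_len(n_v)) k[a, b] <- k[a, b] / tot
    }
    for (a in seq_len(n_v)) {
      acc <- 0
      for (b in seq_len(n_v)) acc <- acc + k[a, b] * pmf[b, j]
      out[a, j] <- acc
    }
  }
  out / sum(out)
}

# Replay an outcome sequence (single option) through update + transition.
oracle_replay <- function(g, outcomes, kind = c("reversal", "drift")) {
  kind <- match.arg(kind)
  pmf <- oracle_uniform(g)
  for (x in outcomes) {
    pmf <- oracle_update(g, pmf, x)
    pmf <- if (kind == "reversal") {
      oracle_transition_reversal(g, pmf)
    } else {
      oracle_transition_drift(g, pmf)
    }
  }
  pmf
}

# Same replay through the package implementation.
package_replay <- function(grid, outcomes) {
  b <- init_belief(grid)
  transition <- if (grid$aux_kind == "reversal_rate") {
    transition_reversal
  } else {
    transition_drift
  }
  for (x in outcomes) b <- transition(bayes_update(b, x))
  b$pmf
}
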