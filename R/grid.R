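# Hypothesis grids and belief containers for the grid-based observer.

#' Construct a hypothesis grid
#'
#' The observer represents beliefs about one option as a joint probability
#' mass function over a discrete hypothesis grid: reward probability
#' (value) on one axis and an auxiliary volatility parameter on the other.
#' For the latent-state model (model 2) the auxiliary axis is the reversal
#' rate `H`; for the drift model (model 1) it is the standard deviation of
#' a Gaussian drift kernel.
#'
#' Defaults follow the standard parameterisation: 101 equally spaced value
#' points on \[0, 1\] (step 0.01) and 31 equally spaced auxiliary points on
#' \[0, 0.3\] (step 0.01).
#'
#' @param aux_kind `"reversal_rate"` (model 2) or `"drift_sd"` (model 1).
#' @param n_v Number of value grid points spanning \[0, 1\].
#' @param n_aux Number of auxiliary grid points spanning `aux_max`.
#' @param aux_max Upper bound of the auxiliary grid.
#' @return An object of class `rb_grid`: a list with `v` (value grid),
#'   `aux` (auxiliary grid) and `aux_kind`.
#' @examples
#' g <- hypothesis_grid("reversal_rate")
#' length(g$v)   # 101
#' range(g$aux)  # 0 0.3
#' @export
hypothesis_grid <- function(aux_kind = c("reversal_rate", "drift_sd"),
                            n_v = 101L, n_aux = 31L, aux_max = 0.3) {
  aux_kind <- match.arg(aux_kind)
  stopifnot(n_v >= 2L, n_aux >= 2L, aux_max > 0)
  structure(
    list(
      v = seq(0, 1, length.out = n_v),
      aux = seq(0, aux_max, length.out = n_aux),
      aux_kind = aux_kind
    ),
    class = "rb_grid"
  )
}

#' @export
print.rb_grid <- function(x, ...) {
  cat(sprintf(
    "<rb_grid> %d value points on [0,1] x %d %s points on [0,%g]\n",
    length(x$v), length(x$aux), x$aux_kind, max(x$aux)
  ))
  invisible(x)
}

grid_for_model <- function(model) {
  model <- match_model(model)
  if (model == "model2") hypothesis_grid("reversal_rate") else hypothesis_grid("drift_sd")
}

match_model <- function(model) {
  model <- as.character(model)
  if (model %in% c("1", "model1")) return("model1")
  if (model %in% c("2", "model2")) return("model2")
  rlang::abort(sprintf("unknown model id '%s' (use \"model1\" or \"model2\")", model))
}

new_belief <- function(grid, pmf) {
  stopifnot(inherits(grid, "rb_grid"),
            nrow(pmf) == length(grid$v), ncol(pmf) == length(grid$aux))
  structure(list(grid = grid, pmf = pmf), class = "rb_belief")
}

#' Initialise a uniform belief over a hypothesis grid
#'
#' Before any outcome is observed, the belief over value and over the
#' auxiliary parameter is uniform over the full hypothesis space.
#'
#' @param grid An [hypothesis_grid()].
#' @return An `rb_belief`: list with the `grid` and a normalized `pmf`
#'   matrix (values in rows, auxiliary points in columns).
#' @examples
#' b <- init_belief(hypothesis_grid("reversal_rate"))
#' sum(b$pmf)  # 1
#' @export
init_belief <- function(grid) {
  n <- length(grid$v) * length(grid$aux)
  new_belief(grid, matrix(1 / n, length(grid$v), length(grid$aux)))
}

#' @export
print.rb_belief <- function(x, ...) {
  cat(sprintf(
    "<rb_belief> %dx%d pmf over (value, %s); E[v] = %.3f\n",
    nrow(x$pmf), ncol(x$pmf), x$grid$aux_kind,
    sum(x$grid$v * rowSums(x$pmf))
  ))
  invisible(x)
}

#' Marginal distributions of a belief
#'
#' @param belief An `rb_belief`.
#' @return A numeric vector of probability mass over the value grid
#'   (`value_marginal`) or over the auxiliary grid (`aux_marginal`).
#' @export
value_marginal <- function(belief) rowSums(belief$pmf)

#' @rdname value_marginal
#' @export
aux_marginal <- function(belief) colSums(belief$pmf)

# Renormalize a pmf matrix, flooring at a tiny positive constant first so a
# numerically all-zero product is caught rather than silently propagated.
normalize_pmf <- function(pmf) {
  pmf[pmf < 0] <- 0
  total <- sum(pmf)
  if (!is.finite(total) || total <= 0) {
    rlang::abort(paste0(
      "belief mass underflowed to zero during an update; ",
      "this cannot happen from a uniform initial belief on the default grid"
    ))
  }
  pmf <- pmf + 1e-300
  pmf / sum(pmf)
}
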