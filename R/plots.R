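# ggplot2 helpers for schedules, switch rates and group coefficients.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a reward schedule
#'
#' Per-trial reward probability of both options, with reversal trials
#' marked.
#'
#' @param object An `rb_schedule`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rb_schedule <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("trial", "p_left", "p_right")],
    cols = c("p_left", "p_right"),
    names_to = "option", values_to = "p"
  )
  revs <- attr(object, "reversal_trials")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$trial, .data$p,
                                          colour = .data$option)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "Trial", y = "Reward probability",
      title = sprintf("%s schedule", attr(object, "condition") %||% "")
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (length(revs)) {
    p <- p + ggplot2::geom_vline(xintercept = revs, linetype = "dotted",
                                 colour = "grey40")
  }
  p
}

#' Plot switch rates after consecutive non-rewards
#'
#' Group-mean bars with per-session dots, by run length and group.
#'
#' @param rates Output of [consecutive_error_switch()].
#' @param group Grouping column name (default `"condition"`).
#' @return A ggplot.
#' @export
plot_switch_rates <- function(rates, group = "condition") {
  rates <- dplyr::filter(rates, is.finite(.data$switch_rate))
  means <- rates |>
    dplyr::summarise(switch_rate = mean(.data$switch_rate),
                     .by = c("run_length", dplyr::all_of(group)))
  ggplot2::ggplot(means, ggplot2::aes(factor(.data$run_length),
                                      .data$switch_rate,
                                      fill = .data[[group]])) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7, alpha = 0.7) +
    ggplot2::geom_point(
      data = rates,
      ggplot2::aes(colour = .data[[group]]),
      position = ggplot2::position_jitterdodge(jitter.width = 0.1,
                                               dodge.width = 0.8),
      size = 0.8, show.legend = FALSE
    ) +
    ggplot2::labs(x = "Consecutive non-rewards", y = "Switch rate") +
    ggplot2::theme_minimal()
}

#' Plot per-session regression coefficients by group
#'
#' Group-mean bars with per-session dots for each regression term,
#' faceted by term.
#'
#' @param fits Long coefficient table from [fit_switch_regressions()].
#' @param group Grouping column name (default `"condition"`).
#' @return A ggplot.
#' @export
plot_group_coefficients <- function(fits, group = "condition") {
  means <- fits |>
    dplyr::summarise(estimate = mean(.data$estimate),
                     .by = c("term", dplyr::all_of(group)))
  ggplot2::ggplot(means, ggplot2::aes(.data[[group]], .data$estimate,
                                      fill = .data[[group]])) +
    ggplot2::geom_col(width = 0.6, alpha = 0.7) +
    ggplot2::geom_point(data = fits,
                        ggplot2::aes(colour = .data[[group]]),
                        position = ggplot2::position_jitter(width = 0.08),
                        size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30") +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(y = "Coefficient (z-scored regressors)") +
    ggplot2::theme_minimal()
}
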