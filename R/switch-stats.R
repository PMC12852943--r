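# Behavioural statistics: consecutive-error switch rates, per-session
# logistic switch regressions, two-stage group inference, and the
# session-type x error-number ANOVA.

#' Overall switch rate per session
#'
#' @param sessions A trial table; split on `session_id` when present.
#' @return A tibble with `session_id` and `switch_rate` (fraction of
#'   trials 2..n whose choice differs from the previous trial's).
#' @export
switch_rate <- function(sessions) {
  if (!"session_id" %in% names(sessions)) sessions$session_id <- "s1"
  sessions |>
    dplyr::summarise(
      switch_rate = mean(.data$choice[-1] != .data$choice[-dplyr::n()]),
      .by = "session_id"
    )
}

#' Switch rates after runs of consecutive non-rewards
#'
#' A trial `t + 1` contributes an observation at run length `r` when the
#' `r` trials up to and including `t` all took the same option and were
#' all unrewarded (a choice switch or a reward resets the run). Each trial
#' is classified at its exact current run length, so a run that survives
#' to length 3 contributes one observation at each of lengths 1, 2 and 3
#' on successive trials (nested observation counts). The switch rate at
#' run length `r` is the fraction of those trials on which the next
#' choice switched.
#'
#' @param sessions A trial table; split on `session_id` when present.
#' @param max_run Longest run length tabulated (default 3); longer runs
#'   are not counted.
#' @return A tibble with one row per session and run length: `n_obs`,
#'   `n_switch`, `switch_rate` (NA when `n_obs` is 0), and the session's
#'   `condition`/`tus` labels where present.
#' @export
consecutive_error_switch <- function(sessions, max_run = 3L) {
  if (!"session_id" %in% names(sessions)) sessions$session_id <- "s1"
  sessions |>
    dplyr::group_by(.data$session_id) |>
    dplyr::group_modify(function(df, key) {
      meta <- df[1, intersect(c("condition", "tus", "subject_id"), names(df))]
      res <- run_switch_counts(df$choice, df$outcome, max_run)
      dplyr::bind_cols(res, meta)
    }) |>
    dplyr::ungroup()
}

run_switch_counts <- function(choices, outcomes, max_run) {
  n <- length(choices)
  n_obs <- n_switch <- integer(max_run)
  run <- 0L
  for (t in seq_len(n)) {
    if (t > 1L && run >= 1L && run <= max_run) {
      # trial t follows a run of `run` consecutive non-rewards for the
      # option held at t-1; record whether the animal switched now
      n_obs[run] <- n_obs[run] + 1L
      if (choices[t] != choices[t - 1L]) n_switch[run] <- n_switch[run] + 1L
    }
    if (t > 1L && choices[t] != choices[t - 1L]) run <- 0L  # switch resets
    run <- if (outcomes[t] == 0) run + 1L else 0L
  }
  tibble::tibble(
    run_length = seq_len(max_run),
    n_obs = n_obs,
    n_switch = n_switch,
    switch_rate = ifelse(n_obs > 0, n_switch / n_obs, NA_real_)
  )
}

#' Build a per-session switch regression design
#'
#' Assembles the switch/stay response and the regressor set of the two
#' switch-regression variants from an observer trace: `lmem1` uses the
#' chosen-minus-unchosen probability and uncertainty differences plus the
#' reversal estimate; `lmem2` enters the four option terms separately.
#' Regressors are expressed relative to the previously held option (the
#' option whose abandonment defines a switch), the first trial is
#' dropped, and regressors are z-scored within session (scale factors are
#' kept in the `"scales"` attribute).
#'
#' @param trace A [run_observer()] trace for one session (latent-state
#'   model, so the reversal estimate is available).
#' @param variant `"lmem1"` (difference coding, 4 columns with intercept)
#'   or `"lmem2"` (separate option terms, 6 columns with intercept).
#' @param standardize Z-score regressors within session (default TRUE).
#' @return An `rb_design` tibble with columns `trial`, `switch` and the
#'   variant's regressors.
#' @export
build_design <- function(trace, variant = c("lmem1", "lmem2"),
                         standardize = TRUE) {
  variant <- match.arg(variant)
  if (!all(is.finite(trace$left_rev))) {
    rlang::abort("build_design() needs a latent-state (model 2) trace with reversal estimates")
  }
  d <- policy_design(trace, trace)
  if (nrow(d) < 10L) rlang::abort("fewer than 10 usable trials")
  out <- if (variant == "lmem1") {
    tibble::tibble(
      trial = d$trial,
      switch = d$switch,
      prob_diff = d$chosen_prob - d$unchosen_prob,
      unc_diff = d$chosen_unc - d$unchosen_unc,
      rev_est = d$reversal_estimate
    )
  } else {
    tibble::tibble(
      trial = d$trial,
      switch = d$switch,
      chosen_prob = d$chosen_prob,
      unchosen_prob = d$unchosen_prob,
      chosen_unc = d$chosen_unc,
      unchosen_unc = d$unchosen_unc,
      rev_est = d$reversal_estimate
    )
  }
  reg_cols <- setdiff(names(out), c("trial", "switch"))
  scales <- NULL
  if (standardize) {
    scales <- purrr::map_dfr(reg_cols, function(cl) {
      m <- mean(out[[cl]])
      s <- stats::sd(out[[cl]])
      if (!is.finite(s) || s == 0) {
        rlang::abort(sprintf("regressor '%s' is constant within session", cl))
      }
      out[[cl]] <<- (out[[cl]] - m) / s
      tibble::tibble(term = cl, center = m, scale = s)
    })
  }
  structure(out, variant = variant, scales = scales,
            class = c("rb_design", class(out)))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression of the switch response on the
#' design's regressors (plus an intercept), by Newton/IRLS iterations to
#' a coefficient tolerance of 1e-8 (at most 100 iterations). Standard
#' errors come from the inverse observed information. A diverging
#' coefficient norm (> 25) flags perfect separation; the fit is returned
#' flagged rather than raising an error.
#'
#' @param design An `rb_design` from [build_design()], or any data frame
#'   with a binary `switch` column and numeric regressors (a `trial`
#'   column, if present, is ignored).
#' @return An `rb_irls` object; `tidy()` gives the coefficient table
#'   (`term`, `estimate`, `std_error`, `statistic`), `glance()` the fit
#'   summary (`loglik`, `converged`, `separation`, `n_obs`).
#' @export
logistic_irls <- function(design) {
  reg_cols <- setdiff(names(design), c("trial", "switch", "session_id"))
  y <- design$switch
  stopifnot(all(y %in% c(0, 1)))
  X <- cbind(intercept = 1, as.matrix(design[reg_cols]))
  beta <- rep(0, ncol(X))
  converged <- FALSE
  separation <- FALSE
  loglik_path <- numeric(0)
  for (it in seq_len(100L)) {
    eta <- drop(X %*% beta)
    loglik_path <- c(loglik_path, sum(y * eta - log1p(exp(pmin(eta, 700)))))
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    info <- crossprod(X, X * w)
    step <- tryCatch(solve(info, crossprod(X, y - mu)),
                     error = function(e) NULL)
    if (is.null(step)) { separation <- TRUE; break }
    beta_new <- beta + drop(step)
    if (sqrt(sum(beta_new^2)) > 25) {
      beta <- beta_new
      separation <- TRUE
      break
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  loglik <- sum(y * eta - log1p(exp(pmin(eta, 700))))
  se <- tryCatch({
    mu <- stats::plogis(eta)
    sqrt(diag(solve(crossprod(X, X * pmax(mu * (1 - mu), 1e-10)))))
  }, error = function(e) rep(NA_real_, length(beta)))
  structure(
    list(
      coefficients = tibble::tibble(
        term = colnames(X),
        estimate = unname(beta),
        std_error = unname(se),
        statistic = unname(beta / se)
      ),
      loglik = loglik,
      loglik_path = loglik_path,
      converged = converged && !separation,
      separation = separation,
      n_obs = length(y),
      variant = attr(design, "variant")
    ),
    class = "rb_irls"
  )
}

#' @export
print.rb_irls <- function(x, ...) {
  cat(sprintf("<rb_irls> %d obs, loglik %.2f%s\n", x$n_obs, x$loglik,
              if (x$separation) " [separation]" else ""))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.rb_irls <- function(x, ...) x$coefficients

#' @export
glance.rb_irls <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, converged = x$converged,
                 separation = x$separation, n_obs = x$n_obs)
}

#' Per-session switch regressions over a cohort
#'
#' Runs the latent-state observer (unless traces are supplied), builds the
#' chosen regression design and fits the per-session logistic regression
#' for every session, returning a long coefficient table ready for
#' [group_contrast()] or for refitting full hierarchical models in
#' external software.
#'
#' @param sessions A trial table with `session_id`.
#' @param variant `"lmem1"` or `"lmem2"`.
#' @param grid Optional observer grid.
#' @param traces Optional precomputed model 2 [run_observer()] traces.
#' @return A tibble with one row per session and term: `estimate`,
#'   `std_error`, `statistic`, `separation`, plus session labels.
#' @export
fit_switch_regressions <- function(sessions, variant = "lmem1", grid = NULL,
                                   traces = NULL) {
  if (!"session_id" %in% names(sessions)) sessions$session_id <- "s1"
  traces <- traces %||% run_observer(sessions, model = "model2", grid = grid)
  ids <- unique(sessions$session_id)
  purrr::map_dfr(ids, function(id) {
    ses <- dplyr::filter(sessions, .data$session_id == id)
    tr <- dplyr::filter(traces, .data$session_id == id)
    fit <- logistic_irls(build_design(tr, variant = variant))
    meta <- ses[1, intersect(c("condition", "tus", "subject_id"), names(ses))]
    dplyr::bind_cols(
      tibble::tibble(session_id = id),
      meta[rep(1, nrow(fit$coefficients)), , drop = FALSE],
      fit$coefficients,
      tibble::tibble(separation = fit$separation)
    )
  })
}

#' Two-stage group inference on per-session coefficients
#'
#' Stage two of the two-stage (summary-statistics) approximation to
#' hierarchical inference: per coefficient, a one-sample test of the
#' session coefficients against zero within each group, and a two-sample
#' contrast between each group and a reference group. Parametric (t) and
#' rank (Wilcoxon / Mann-Whitney) variants are both reported.
#'
#' @param fits Long coefficient table from [fit_switch_regressions()].
#' @param group Name of the grouping column (e.g. `"condition"` or
#'   `"tus"`).
#' @param reference Reference group for contrasts; defaults to the first
#'   group level encountered.
#' @param p_adjust Multiple-testing adjustment applied to the contrast
#'   p-values (`"none"` default, or any [stats::p.adjust()] method such as
#'   `"holm"`).
#' @return An `rb_group_result`: list with `$by_group` (per group x term
#'   means and one-sample tests) and `$contrast` (per term x non-reference
#'   group differences and two-sample tests).
#' @export
group_contrast <- function(fits, group, reference = NULL, p_adjust = "none") {
  stopifnot(group %in% names(fits))
  if (!"separation" %in% names(fits)) fits$separation <- FALSE
  fits <- dplyr::filter(fits, !.data$separation | is.na(.data$separation))
  groups <- unique(fits[[group]])
  reference <- reference %||% groups[1]
  counts <- dplyr::count(fits, .data[[group]],
                         .data$term)
  if (any(counts$n < 3)) rlang::abort("need at least 3 sessions per group")

  safe_test <- function(expr) {
    tryCatch(expr, error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  }
  by_group <- fits |>
    dplyr::group_by(.data[[group]], .data$term) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$estimate),
      t_statistic = unname(safe_test(stats::t.test(.data$estimate))$statistic),
      t_p = safe_test(stats::t.test(.data$estimate))$p.value,
      wilcoxon_p = safe_test(stats::wilcox.test(.data$estimate, exact = FALSE))$p.value,
      .groups = "drop"
    )

  contrast <- purrr::map_dfr(setdiff(groups, reference), function(g) {
    purrr::map_dfr(unique(fits$term), function(tm) {
      a <- fits$estimate[fits[[group]] == reference & fits$term == tm]
      b <- fits$estimate[fits[[group]] == g & fits$term == tm]
      tt <- safe_test(stats::t.test(b, a))
      mw <- safe_test(stats::wilcox.test(b, a, exact = FALSE))
      tibble::tibble(
        term = tm, group = g, reference = reference,
        diff = mean(b) - mean(a),
        t_statistic = unname(tt$statistic), t_p = tt$p.value,
        mw_statistic = unname(mw$statistic), mw_p = mw$p.value
      )
    })
  })
  if (nrow(contrast)) {
    # complete ties (all coefficients identical) carry no evidence of a
    # group difference: report p = 1 rather than the NaN of a 0/0 z-score
    contrast$mw_p[is.nan(contrast$mw_p)] <- 1
    contrast$t_p_adj <- stats::p.adjust(contrast$t_p, method = p_adjust)
    contrast$mw_p_adj <- stats::p.adjust(contrast$mw_p, method = p_adjust)
  }
  structure(list(by_group = by_group, contrast = contrast, group = group),
            class = "rb_group_result")
}

#' @export
print.rb_group_result <- function(x, ...) {
  cat(sprintf("<rb_group_result> grouped by '%s'\n\nPer-group tests vs 0:\n", x$group))
  print(x$by_group, n = Inf)
  if (nrow(x$contrast)) {
    cat("\nBetween-group contrasts:\n")
    print(x$contrast, n = Inf)
  }
  invisible(x)
}

#' @export
tidy.rb_group_result <- function(x, ...) x$by_group

#' Session-type by error-number ANOVA on switch rates
#'
#' Two-way analysis of variance of per-session switch rates with factors
#' group (e.g. correlated vs uncorrelated) and consecutive-error run
#' length, one observation per session x run length. Returns the full
#' ANOVA table; the row of interest is the interaction.
#'
#' @param rates Output of [consecutive_error_switch()] (or any tibble with
#'   `switch_rate`, `run_length` and a grouping column); rows with
#'   undefined rates are dropped.
#' @param group Name of the grouping column (default `"condition"`).
#' @return A tibble with `effect`, `df`, `sumsq`, `statistic`, `p_value`;
#'   attribute `"interaction"` holds the interaction row.
#' @export
anova_session_by_errors <- function(rates, group = "condition") {
  stopifnot(all(c("switch_rate", "run_length", group) %in% names(rates)))
  rates <- dplyr::filter(rates, is.finite(.data$switch_rate))
  cells <- table(rates[[group]], rates$run_length)
  if (any(cells == 0)) rlang::abort("empty design cells in the group x run-length layout")
  df <- data.frame(
    rate = rates$switch_rate,
    g = factor(rates[[group]]),
    r = factor(rates$run_length)
  )
  fit <- stats::aov(rate ~ g * r, data = df)
  tab <- summary(fit)[[1]]
  out <- tibble::tibble(
    effect = c(group, "run_length", paste0(group, ":run_length"), "residuals"),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    statistic = tab$`F value`,
    p_value = tab$`Pr(>F)`
  )
  inter <- out[3, ]
  # a layout with literally identical cell means has zero interaction and
  # zero residual variation; report F = 0, p = 1 rather than 0/0
  if (is.finite(inter$sumsq) && inter$sumsq < 1e-12) {
    out$statistic[3] <- 0
    out$p_value[3] <- 1
    inter <- out[3, ]
  }
  attr(out, "interaction") <- inter
  out
}
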