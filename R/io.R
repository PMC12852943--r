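# Tab-separated trial-table, trace and results I/O, and run
# configuration files.

TRIAL_COLS <- c("session_id", "condition", "tus", "trial", "p_left",
                "p_right", "choice", "outcome", "iti_s", "aod_s")

#' Read a trial table
#'
#' Reads a tab-separated trial table (one row per trial), groups rows by
#' `session_id` and sorts trials within session. Behavioural columns may
#' be absent (schedule-only files), but when present they are validated:
#' outcomes must be 0/1 and choices `L`/`R`; duplicate `(session_id,
#' trial)` pairs are an error.
#'
#' @param path File path.
#' @return A tibble sorted by `(session_id, trial)`.
#' @export
read_trial_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("session_id", "trial")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    rlang::abort(paste0("trial table is missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  dup <- duplicated(df[c("session_id", "trial")])
  if (any(dup)) {
    rlang::abort(sprintf("duplicate (session_id, trial) pair at row %d",
                         which(dup)[1]))
  }
  if ("outcome" %in% names(df)) {
    bad <- which(!is.na(df$outcome) & !df$outcome %in% c(0, 1))
    if (length(bad)) {
      rlang::abort(sprintf("non-binary outcome at row %d (value %s)",
                           bad[1], df$outcome[bad[1]]))
    }
  }
  if ("choice" %in% names(df)) {
    bad <- which(!is.na(df$choice) & !df$choice %in% c("L", "R"))
    if (length(bad)) {
      rlang::abort(sprintf("invalid choice at row %d (value %s); expected L or R",
                           bad[1], df$choice[bad[1]]))
    }
  }
  dplyr::arrange(df, .data$session_id, .data$trial)
}

# Format numeric columns at 10 significant digits so output files are
# deterministic and round-trip within 1e-9 relative error.
format_table <- function(df) {
  dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double),
    ~ formatC(.x, digits = 10, format = "g")
  ))
}

write_tsv_10sig <- function(df, path) {
  readr::write_tsv(format_table(df), path, progress = FALSE)
  invisible(path)
}

#' Write trial, trace and results tables
#'
#' Tab-separated writers with a deterministic column order and floats at
#' 10 significant digits, so identical inputs give byte-identical files.
#' `write_trial_table()` puts the canonical trial columns first
#' (`session_id, condition, tus, trial, p_left, p_right, choice, outcome,
#' iti_s, aod_s`) and keeps any extra columns (e.g. `subject_id`) after
#' them.
#'
#' @param sessions,trace,fits Tibbles to write.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trial_table <- function(sessions, path) {
  lead <- intersect(TRIAL_COLS, names(sessions))
  write_tsv_10sig(sessions[c(lead, setdiff(names(sessions), lead))], path)
}

#' @rdname write_trial_table
#' @export
write_trace_table <- function(trace, path) {
  lead <- intersect(c("session_id", "trial"), names(trace))
  write_tsv_10sig(trace[c(lead, setdiff(names(trace), lead))], path)
}

#' @rdname write_trial_table
#' @export
write_results <- function(fits, path) {
  write_tsv_10sig(fits, path)
}

#' Read an observer trace table
#'
#' @param path File path.
#' @return A tibble sorted by `(session_id, trial)`.
#' @export
read_trace_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("session_id", "trial") %in% names(df))) {
    df <- dplyr::arrange(df, .data$session_id, .data$trial)
  }
  df
}

#' Read and validate a run configuration
#'
#' YAML configuration with nested sections `task` (schedule generator
#' parameters), `observer` (model and grid), `agent` (policy preset and
#' seed) and `analysis` (regression variant). Missing sections get
#' defaults; unknown section names are an error.
#'
#' @param path YAML file path.
#' @return An `rb_config` list with sections `task`, `observer`, `agent`,
#'   `analysis`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("task", "observer", "agent", "analysis", "timing")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    rlang::abort(paste0("unknown config section(s): ",
                        paste(unknown, collapse = ", ")))
  }
  cfg <- list(
    task = utils::modifyList(list(
      condition = "correlated", n_sessions = 4L, n_trials = 170L
    ), raw$task %||% list()),
    observer = utils::modifyList(list(model = "model2"), raw$observer %||% list()),
    agent = utils::modifyList(list(preset = "sham", seed = 1L), raw$agent %||% list()),
    analysis = utils::modifyList(list(variant = "lmem1"), raw$analysis %||% list())
  )
  if (!cfg$task$condition %in% c("correlated", "uncorrelated")) {
    rlang::abort("task$condition must be 'correlated' or 'uncorrelated'")
  }
  structure(cfg, class = "rb_config")
}
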