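# Trial-record I/O and summaries.
#
# A trial-record data frame has one row per stimulus presentation with
# columns: subject_id, element_size_deg, step_size_deg, direction (-1/+1)
# and response ("left"/"right"/"other"). `detected` marks trials where the
# response sign matched the stimulus direction; opposite-direction responses
# count as not detected.

trial_columns <- c("subject_id", "element_size_deg", "step_size_deg",
                   "direction", "response")

response_levels <- c("left", "right", "other")

# response sign convention: right = +1, left = -1, other = 0
response_sign <- function(response) {
  c(left = -1, right = 1, other = 0)[response]
}

#' Mark detected trials
#'
#' A trial counts as detected when the coded response direction equals the
#' stimulus direction (`right` with direction +1, `left` with direction -1).
#'
#' @param trials Trial-record data frame.
#' @return The data frame with a logical `detected` column (re)computed.
#' @export
mark_detected <- function(trials) {
  validate_trials(trials)
  trials$detected <- unname(response_sign(trials$response) == trials$direction)
  trials
}

validate_trials <- function(trials) {
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols) > 0) {
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!(trials$response %in% response_levels))
  if (length(bad) > 0) {
    stop(sprintf(
      "parse error: invalid response %s in row %d (must be left/right/other)",
      dQuote(trials$response[bad[1]]), bad[1]
    ))
  }
  bad_dir <- which(!(trials$direction %in% c(-1, 1)))
  if (length(bad_dir) > 0) {
    stop(sprintf("parse error: invalid direction %s in row %d (must be -1 or 1)",
                 trials$direction[bad_dir[1]], bad_dir[1]))
  }
  invisible(trials)
}

#' Read trial records from CSV
#'
#' Expects a UTF-8 CSV with header and at least the columns `subject_id`,
#' `element_size_deg`, `step_size_deg`, `direction` and `response`; unknown
#' columns are preserved. A file with a header only yields an empty (but
#' valid) dataset.
#'
#' @param path Path to the CSV file, or a vector of paths whose records are
#'   pooled (row-bound) in order.
#' @return Trial-record data frame with a `detected` column.
#' @export
read_trials <- function(path) {
  parts <- lapply(path, function(p) {
    utils::read.csv(p, stringsAsFactors = FALSE, encoding = "UTF-8")
  })
  common <- Reduce(intersect, lapply(parts, names))
  trials <- do.call(rbind, lapply(parts, function(d) d[common]))
  if (nrow(trials) == 0) {
    validate_trials(trials[trial_columns[trial_columns %in% names(trials)]])
    missing_cols <- setdiff(trial_columns, names(trials))
    if (length(missing_cols) > 0) {
      stop(sprintf("schema error: missing required column(s): %s",
                   paste(missing_cols, collapse = ", ")))
    }
    trials$detected <- logical(0)
    return(trials)
  }
  mark_detected(trials)
}

#' Write trial records to CSV
#'
#' @param trials Trial-record data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-condition detection counts
#'
#' Pools trials over subjects and directions into the condition summary used
#' for psychometric fitting: for each (element size, step size), the number
#' of trials `n_total` and the number in which motion was detected
#' `n_detected`.
#'
#' @param trials Trial-record data frame.
#' @return Data frame with `element_size_deg`, `step_size_deg`, `n_detected`,
#'   `n_total`, sorted by element then step.
#' @export
condition_summary <- function(trials) {
  trials <- mark_detected(trials)
  agg <- stats::aggregate(
    cbind(n_detected = trials$detected, n_total = rep(1L, nrow(trials))),
    by = list(element_size_deg = trials$element_size_deg,
              step_size_deg = trials$step_size_deg),
    FUN = sum
  )
  agg <- agg[order(agg$element_size_deg, agg$step_size_deg), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
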