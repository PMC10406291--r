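# Criteria B (improper task presentation) and C (invalid task performance),
# decided from the events table. A "no-response" trial is one whose response
# key is missing; a recorded response with unknown correctness still counts
# as a response.

#' Check observed trial counts against expectations
#'
#' A count mismatch (wrong number of trials of a type, or a type that was
#' never expected) is a QC finding feeding criterion B, not an error.
#'
#' @param events an [events_table()].
#' @param expected_by_type named integer vector/list of expected trial
#'   counts per `trial_type`, e.g. `c(CONTROL = 32, TASK = 32)`.
#' @return List with `counts` (observed per-type counts), `expected`,
#'   `counts_mismatch` (logical) and `messages` (character vector
#'   enumerating each mismatch; empty when counts agree).
#' @export
check_trial_counts <- function(events, expected_by_type) {
  stopifnot(inherits(events, "events_table"))
  expected <- unlist(expected_by_type)
  if (length(expected) == 0L || is.null(names(expected)))
    .stopf("expected_by_type must be a non-empty named vector")
  obs <- table(events$trial_type)
  counts <- stats::setNames(as.integer(obs), names(obs))
  msgs <- character()
  for (ty in names(expected)) {
    got <- if (ty %in% names(counts)) counts[[ty]] else 0L
    if (got != expected[[ty]])
      msgs <- c(msgs, sprintf("trial_type '%s': expected %d, observed %d",
                              ty, as.integer(expected[[ty]]), got))
  }
  for (ty in setdiff(names(counts), names(expected)))
    msgs <- c(msgs, sprintf("unexpected trial_type '%s' observed %d time(s)",
                            ty, counts[[ty]]))
  list(counts = counts, expected = expected,
       counts_mismatch = length(msgs) > 0L, messages = msgs)
}

#' Decide criterion B (improper task presentation)
#'
#' The run is excluded when fewer than half of the expected trials have
#' usable data; exactly half keeps the run (the comparison is strict).
#' By default "usable" means the trial's event row is present (the
#' run-truncation model); an externally derived count — e.g. trials
#' unaffected by censoring from [trial_censor_overlap()] — may be supplied
#' instead.
#'
#' @param events an [events_table()].
#' @param expected_total expected number of trials in a complete run.
#' @param usable_trials number of usable trials; defaults to the observed
#'   trial count.
#' @param min_fraction exclusion boundary (default 0.5).
#' @return List with `criterion_b_exclude` (logical), `usable_fraction`,
#'   `usable_trials`, `expected_total`.
#' @export
evaluate_criterion_b <- function(events, expected_total,
                                 usable_trials = NULL, min_fraction = 0.5) {
  stopifnot(inherits(events, "events_table"))
  .assert_scalar_number(expected_total, "expected_total", min = 0,
                        strict_min = TRUE)
  if (is.null(usable_trials)) usable_trials <- nrow(events)
  if (usable_trials < 0 || usable_trials > expected_total)
    .stopf("usable_trials must be in [0, expected_total]")
  frac <- usable_trials / expected_total
  list(criterion_b_exclude = frac < min_fraction,
       usable_fraction = frac,
       usable_trials = usable_trials,
       expected_total = expected_total)
}

#' Longest streak of consecutive no-response trials
#'
#' Trials are taken in onset order (guaranteed by [events_table()]).
#'
#' @param events an [events_table()].
#' @return Integer: length of the longest maximal block of trials with a
#'   missing response; 0 when every trial was responded to.
#' @export
longest_no_response_run <- function(events) {
  stopifnot(inherits(events, "events_table"))
  if (nrow(events) == 0L) .stopf("events table is empty")
  miss <- is.na(events$response)
  r <- rle(miss)
  streaks <- r$lengths[r$values]
  if (length(streaks) == 0L) 0L else max(streaks)
}

#' Decide criterion C (invalid task performance)
#'
#' The run is excluded when the participant failed to respond to
#' `max_run` or more trials in a row (inclusive), or to more than
#' `max_frac` of all trials (strict). The two components are reported
#' separately so the report can distinguish inattentiveness patterns.
#'
#' @param events an [events_table()].
#' @param max_run streak threshold, trials (default 5, "five or more in a
#'   row").
#' @param max_frac fraction threshold (default 0.40, "more than 40
#'   percent").
#' @return List with `criterion_c_exclude`, `exclude_by_run`,
#'   `exclude_by_fraction`, `longest_no_response_run`, `n_no_response`,
#'   `frac_no_response`.
#' @export
evaluate_criterion_c <- function(events, max_run = 5L, max_frac = 0.40) {
  stopifnot(inherits(events, "events_table"))
  n <- nrow(events)
  if (n == 0L) .stopf("events table is empty")
  streak <- longest_no_response_run(events)
  n_miss <- sum(is.na(events$response))
  frac <- n_miss / n
  by_run <- streak >= max_run          # inclusive: "five or more"
  by_frac <- frac > max_frac           # strict: "more than 40 percent"
  list(criterion_c_exclude = by_run || by_frac,
       exclude_by_run = by_run,
       exclude_by_fraction = by_frac,
       longest_no_response_run = streak,
       n_no_response = n_miss,
       frac_no_response = frac)
}

#' Summarize responses by key, with accuracy among responded trials
#'
#' The accuracy denominator is responded trials only: a no-response trial
#' is neither correct nor incorrect. When no correctness information is
#' present, accuracy is `NA` (suppressed, not zeroed).
#'
#' @param events an [events_table()].
#' @return List with `n_responses_by_key` (named integer vector),
#'   `n_responses_total`, `n_no_response`, `accuracy_responded`.
#' @export
response_summary <- function(events) {
  stopifnot(inherits(events, "events_table"))
  responded <- !is.na(events$response)
  by_key <- table(events$response[responded])
  n_resp <- sum(responded)
  acc <- if (n_resp > 0L && any(!is.na(events$correct[responded])))
    sum(events$correct[responded], na.rm = TRUE) / n_resp
  else NA_real_
  list(n_responses_by_key = stats::setNames(as.integer(by_key),
                                            names(by_key)),
       n_responses_total = n_resp,
       n_no_response = nrow(events) - n_resp,
       accuracy_responded = acc)
}

#' Flag single-button responding
#'
#' A participant who pressed only one key throughout may not have been
#' performing the task. This is a review flag feeding the qualitative part
#' of criterion C, never an automatic exclusion; it requires at least
#' `min_responses` responses as evidence.
#'
#' @param events an [events_table()].
#' @param min_responses minimum responses before the flag can fire
#'   (default 10).
#' @return Logical.
#' @export
detect_single_button <- function(events, min_responses = 10L) {
  rs <- response_summary(events)
  rs$n_responses_total >= min_responses &&
    sum(rs$n_responses_by_key > 0L) == 1L
}

#' Full behavioral QC for one run
#'
#' Assembles trial counts, criterion B, criterion C and the response
#' summary into one record.
#'
#' @param events an [events_table()].
#' @param expected_by_type optional named expected per-type counts (the
#'   study design must supply these; they cannot be inferred from data).
#' @param expected_total expected trial total; defaults to
#'   `sum(expected_by_type)` when given, else the observed count.
#' @param max_run,max_frac criterion-C thresholds, see
#'   [evaluate_criterion_c()].
#' @param min_responses see [detect_single_button()].
#' @param usable_trials see [evaluate_criterion_b()].
#' @return An object of class `behavior_result`: all component results
#'   plus a `flags` list (`criterion_b_exclude`, `criterion_c_exclude`,
#'   `single_button`, `counts_mismatch`).
#' @export
evaluate_behavior <- function(events, expected_by_type = NULL,
                              expected_total = NULL,
                              max_run = 5L, max_frac = 0.40,
                              min_responses = 10L, usable_trials = NULL) {
  stopifnot(inherits(events, "events_table"))
  n <- nrow(events)
  counts <- if (!is.null(expected_by_type))
    check_trial_counts(events, expected_by_type)
  else list(counts = stats::setNames(as.integer(table(events$trial_type)),
                                     names(table(events$trial_type))),
            expected = NULL, counts_mismatch = FALSE, messages = character())
  if (is.null(expected_total))
    expected_total <- if (!is.null(expected_by_type))
      sum(unlist(expected_by_type)) else n
  b <- evaluate_criterion_b(events, expected_total, usable_trials)
  c_res <- evaluate_criterion_c(events, max_run, max_frac)
  rs <- response_summary(events)
  structure(
    list(run_id = attr(events, "run_id"),
         n_trials = n,
         counts_by_type = counts$counts,
         expected_by_type = counts$expected,
         count_messages = counts$messages,
         usable_fraction = b$usable_fraction,
         n_responses_by_key = rs$n_responses_by_key,
         n_responses_total = rs$n_responses_total,
         n_no_response = rs$n_no_response,
         frac_no_response = c_res$frac_no_response,
         longest_no_response_run = c_res$longest_no_response_run,
         exclude_by_run = c_res$exclude_by_run,
         exclude_by_fraction = c_res$exclude_by_fraction,
         accuracy_responded = rs$accuracy_responded,
         flags = list(criterion_b_exclude = b$criterion_b_exclude,
                      criterion_c_exclude = c_res$criterion_c_exclude,
                      single_button = detect_single_button(events,
                                                           min_responses),
                      counts_mismatch = counts$counts_mismatch)),
    class = "behavior_result")
}

#' @export
print.behavior_result <- function(x, ...) {
  cat(sprintf("<behavior_result> run '%s': %d trials, %d responses (%s)\n",
              x$run_id, x$n_trials, x$n_responses_total,
              paste(sprintf("%s=%d", names(x$n_responses_by_key),
                            x$n_responses_by_key), collapse = ", ")))
  cat(sprintf("  no-response: %d (%.1f%%), longest streak %d; accuracy %s\n",
              x$n_no_response, 100 * x$frac_no_response,
              x$longest_no_response_run,
              if (is.na(x$accuracy_responded)) "n/a"
              else sprintf("%.2f", x$accuracy_responded)))
  on <- names(Filter(isTRUE, x$flags))
  cat(sprintf("  flags: %s\n", if (length(on)) paste(on, collapse = ", ")
              else "none"))
  invisible(x)
}
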