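# Criterion A: excessive motion. Frames with FD above threshold are
# censored; a run whose censored fraction reaches the exclusion fraction is
# dropped entirely.

#' Compute framewise displacement
#'
#' Power-style FD: per frame, the sum of absolute backward differences of
#' the three translations (mm) plus the three rotations converted to arc
#' length on a reference sphere (default radius 50 mm). The first frame has
#' no predecessor, so `fd[1] = 0`.
#'
#' @param motion a [motion_record()] (its stored `fd` is ignored), or a
#'   list with `trans` and `rot` n-by-3 matrices.
#' @param head_radius_mm sphere radius used to convert radians to mm.
#' @return Numeric vector of per-frame FD values, mm.
#' @export
compute_fd <- function(motion, head_radius_mm = 50) {
  .assert_scalar_number(head_radius_mm, "head_radius_mm", min = 0)
  trans <- as.matrix(motion$trans); rot <- as.matrix(motion$rot)
  if (any(!is.finite(trans)) || any(!is.finite(rot)))
    .stopf("motion parameters must be finite")
  n <- nrow(trans)
  if (n == 1L) return(0)
  dt <- abs(diff(trans)); dr <- abs(diff(rot))
  c(0, rowSums(dt) + head_radius_mm * rowSums(dr))
}

#' Censor high-motion frames
#'
#' A frame is censored when its FD strictly exceeds `threshold_mm`
#' ("more than 0.9 mm FD"); a value exactly at the threshold is kept.
#' Optionally extends censoring to neighbouring frames.
#'
#' @param fd per-frame FD series (mm, non-negative), or a
#'   [motion_record()].
#' @param threshold_mm censoring threshold in mm (default 0.9).
#' @param frac_threshold run-exclusion fraction passed through to
#'   [evaluate_criterion_a()] (default 0.20).
#' @param censor_before,censor_after integers: additionally censor this
#'   many frames before/after each supra-threshold frame (default 0, i.e.
#'   single-frame censoring).
#' @param run_id run identifier; taken from the motion record if given.
#' @return An object of class `censor_result`: list with `run_id`,
#'   `threshold_mm`, `censor_mask` (logical, `TRUE` = censored),
#'   `censored_frame_indices`, `n_frames`, `n_censored`, `frac_censored`,
#'   `frac_threshold`, `exclude_run`.
#' @export
censor_frames <- function(fd, threshold_mm = 0.9, frac_threshold = 0.20,
                          censor_before = 0L, censor_after = 0L,
                          run_id = NULL) {
  if (inherits(fd, "motion_record")) {
    if (is.null(run_id)) run_id <- fd$run_id
    fd <- fd$fd
  }
  if (is.null(run_id)) run_id <- "run"
  .assert_scalar_number(threshold_mm, "threshold_mm", min = 0)
  fd <- as.numeric(fd)
  if (any(!is.finite(fd)) || any(fd < 0))
    .stopf("fd values must be finite and >= 0")
  n <- length(fd)
  mask <- fd > threshold_mm            # strict: exactly-at-threshold kept
  if (censor_before > 0L || censor_after > 0L) {
    hits <- which(mask)
    for (h in hits) {
      lo <- max(1L, h - as.integer(censor_before))
      hi <- min(n, h + as.integer(censor_after))
      mask[lo:hi] <- TRUE
    }
  }
  res <- structure(
    list(run_id = as.character(run_id),
         threshold_mm = threshold_mm,
         censor_mask = mask,
         censored_frame_indices = which(mask),
         n_frames = n,
         n_censored = sum(mask),
         frac_censored = sum(mask) / n,
         frac_threshold = frac_threshold,
         exclude_run = NA),
    class = "censor_result")
  res$exclude_run <- evaluate_criterion_a(res, frac_threshold)
  res
}

#' @export
print.censor_result <- function(x, ...) {
  cat(sprintf(
    "<censor_result> run '%s': %d/%d frames censored (%.1f%%, FD > %g mm) -> %s\n",
    x$run_id, x$n_censored, x$n_frames, 100 * x$frac_censored,
    x$threshold_mm, if (x$exclude_run) "EXCLUDE run" else "keep run"))
  invisible(x)
}

#' Decide criterion A (excessive motion) for a run
#'
#' The run is excluded when the censored fraction is greater than or equal
#' to `frac_threshold` ("20\% or more of the frames"). The comparison is
#' inclusive by default; pass `inclusive = FALSE` for the strict reading.
#'
#' @param censor a `censor_result` from [censor_frames()].
#' @param frac_threshold exclusion fraction (default 0.20).
#' @param inclusive use `>=` (default) rather than `>`.
#' @return Logical: `TRUE` when the run should be excluded.
#' @export
evaluate_criterion_a <- function(censor, frac_threshold = 0.20,
                                 inclusive = TRUE) {
  .assert_scalar_number(frac_threshold, "frac_threshold", min = 0)
  if (inclusive) censor$frac_censored >= frac_threshold
  else censor$frac_censored > frac_threshold
}

#' Overlap between task trials and censored frames
#'
#' Motion outside trials removes fewer analyzable trials than motion during
#' them, so the timing of censored frames relative to trials is a useful
#' refinement of criterion A. A trial counts as affected when any censored
#' frame's acquisition time falls in `[onset, onset + duration)`.
#'
#' @param events an [events_table()].
#' @param censor a `censor_result` from [censor_frames()].
#' @param frame_times per-frame acquisition times in seconds, strictly
#'   increasing, one per frame (typically `(0:(n-1)) * TR`).
#' @return An object of class `trial_censor_overlap`: list with
#'   `trial_affected` (logical per trial), `n_trials_affected`,
#'   `n_censored_in_trials`, `n_censored_outside_trials`.
#' @export
trial_censor_overlap <- function(events, censor, frame_times) {
  stopifnot(inherits(events, "events_table"),
            inherits(censor, "censor_result"))
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) != censor$n_frames)
    .stopf("frame_times has %d entries but the run has %d frames",
           length(frame_times), censor$n_frames)
  if (any(diff(frame_times) <= 0))
    .stopf("frame_times must be strictly increasing")
  ctimes <- frame_times[censor$censor_mask]
  onset <- events$onset; offset <- events$onset + events$duration
  affected <- vapply(seq_len(nrow(events)), function(i)
    any(ctimes >= onset[i] & ctimes < offset[i]), logical(1L))
  in_trials <- vapply(ctimes, function(tm)
    any(tm >= onset & tm < offset), logical(1L))
  structure(
    list(trial_affected = affected,
         n_trials_affected = sum(affected),
         n_censored_in_trials = sum(in_trials),
         n_censored_outside_trials = sum(!in_trials)),
    class = "trial_censor_overlap")
}
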