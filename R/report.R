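# Per-run and dataset-level QC reports: motion plots, behavioral raster,
# image montage grids, and the machine-readable decision record. Two HTML
# documents mirror the classic split between an image/motion report and a
# behavioral report.

#' Record a QC decision for one run
#'
#' Criteria A-C are quantitative pass/fail. Criterion D is qualitative:
#' the tool can only emit `"pass"` or `"needs_review"`; a `"fail"` must
#' come from a human override and always carries a note.
#'
#' @param run_id run identifier.
#' @param criterion_a,criterion_b,criterion_c `"pass"` or `"fail"`.
#' @param criterion_d `"pass"`, `"needs_review"` or `"fail_by_override"`.
#' @param override_note free text justifying a criterion-D override;
#'   required when `criterion_d = "fail_by_override"`.
#' @return An object of class `qc_decision` with an `excluded` flag that
#'   is `TRUE` iff any criterion is fail / fail_by_override.
#' @export
qc_decision <- function(run_id,
                        criterion_a = c("pass", "fail"),
                        criterion_b = c("pass", "fail"),
                        criterion_c = c("pass", "fail"),
                        criterion_d = c("pass", "needs_review",
                                        "fail_by_override"),
                        override_note = NULL) {
  criterion_a <- match.arg(criterion_a)
  criterion_b <- match.arg(criterion_b)
  criterion_c <- match.arg(criterion_c)
  criterion_d <- match.arg(criterion_d)
  if (criterion_d == "fail_by_override" &&
      (is.null(override_note) || !nzchar(override_note)))
    .stopf("criterion D can only fail through a recorded human override; supply override_note")
  structure(
    list(run_id = as.character(run_id),
         criterion_a = criterion_a, criterion_b = criterion_b,
         criterion_c = criterion_c, criterion_d = criterion_d,
         excluded = any(c(criterion_a, criterion_b, criterion_c) == "fail") ||
           criterion_d == "fail_by_override",
         override_note = override_note),
    class = "qc_decision")
}

#' Derive a run's QC decision from its quantitative results
#'
#' @param censor a `censor_result` or `NULL` (criterion A passes
#'   vacuously when motion was not assessed).
#' @param behavior a `behavior_result` or `NULL`.
#' @param needs_review logical: metadata/image evidence flagged this run
#'   for criterion-D review.
#' @param override optional list `list(criterion = "D", status = "fail",
#'   note = "...")` recording a human judgment.
#' @param run_id run identifier (defaults to the censor/behavior run).
#' @return A [qc_decision()].
#' @export
decide_run <- function(censor = NULL, behavior = NULL,
                       needs_review = FALSE, override = NULL,
                       run_id = NULL) {
  if (is.null(run_id))
    run_id <- if (!is.null(censor)) censor$run_id
              else if (!is.null(behavior)) behavior$run_id
              else .stopf("run_id required when no results are supplied")
  a <- if (!is.null(censor) && isTRUE(censor$exclude_run)) "fail" else "pass"
  b <- if (!is.null(behavior) &&
           isTRUE(behavior$flags$criterion_b_exclude)) "fail" else "pass"
  cc <- if (!is.null(behavior) &&
            isTRUE(behavior$flags$criterion_c_exclude)) "fail" else "pass"
  d <- if (needs_review) "needs_review" else "pass"
  note <- NULL
  if (!is.null(override) && identical(override$criterion, "D") &&
      identical(override$status, "fail")) {
    d <- "fail_by_override"
    note <- override$note
  }
  qc_decision(run_id, a, b, cc, d, override_note = note)
}

#' @export
print.qc_decision <- function(x, ...) {
  cat(sprintf("<qc_decision> run '%s': A=%s B=%s C=%s D=%s -> %s\n",
              x$run_id, x$criterion_a, x$criterion_b, x$criterion_c,
              x$criterion_d,
              if (x$excluded) "EXCLUDED" else "included"))
  invisible(x)
}

# Decision record as a plain list for JSON serialization.
.decision_record <- function(d) {
  list(run_id = d$run_id,
       criterion_a = d$criterion_a, criterion_b = d$criterion_b,
       criterion_c = d$criterion_c, criterion_d = d$criterion_d,
       excluded = d$excluded,
       override_note = if (is.null(d$override_note)) NA else d$override_note)
}

#' Motion QC figure for one run
#'
#' Line plots of the six realignment parameters and FD, with trial onsets,
#' the censoring threshold, and censored frames marked; the censored count
#' and fraction are printed on the FD panel so they can be compared to the
#' run-exclusion criterion at a glance.
#'
#' @param motion a [motion_record()].
#' @param censor the matching `censor_result`.
#' @param events optional [events_table()] for trial-onset marks.
#' @param path output PNG path.
#' @param tr_s repetition time used to place frames on the time axis.
#' @return `path`, invisibly.
#' @export
motion_figure <- function(motion, censor, events = NULL, path,
                          tr_s = 2) {
  stopifnot(inherits(motion, "motion_record"),
            inherits(censor, "censor_result"))
  if (!identical(motion$run_id, censor$run_id))
    .stopf("motion (%s) and censor (%s) refer to different runs",
           motion$run_id, censor$run_id)
  if (!is.null(events) &&
      !identical(attr(events, "run_id"), motion$run_id))
    .stopf("events (%s) and motion (%s) refer to different runs",
           attr(events, "run_id"), motion$run_id)
  tt <- (seq_len(motion$n_frames) - 1L) * tr_s
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 2, 1), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op), add = TRUE)
  mark_onsets <- function() if (!is.null(events))
    graphics::abline(v = events$onset, col = "grey85")
  graphics::matplot(tt, motion$trans, type = "l", lty = 1,
                    col = c("firebrick", "forestgreen", "dodgerblue"),
                    xlab = "time (s)", ylab = "translation (mm)",
                    main = sprintf("run %s: realignment parameters",
                                   motion$run_id))
  mark_onsets()
  graphics::legend("topright", c("x", "y", "z"), lty = 1, bty = "n",
                   col = c("firebrick", "forestgreen", "dodgerblue"))
  graphics::matplot(tt, motion$rot, type = "l", lty = 1,
                    col = c("firebrick", "forestgreen", "dodgerblue"),
                    xlab = "time (s)", ylab = "rotation (rad)")
  mark_onsets()
  graphics::plot(tt, motion$fd, type = "l", col = "black",
                 xlab = "time (s)", ylab = "FD (mm)",
                 ylim = c(0, max(motion$fd, censor$threshold_mm) * 1.15))
  mark_onsets()
  graphics::abline(h = censor$threshold_mm, col = "orange", lty = 2)
  if (censor$n_censored > 0L)
    graphics::points(tt[censor$censor_mask], motion$fd[censor$censor_mask],
                     col = "red", pch = 4, cex = 1.2)
  graphics::mtext(sprintf("censored: %d (%.1f%%)", censor$n_censored,
                          100 * censor$frac_censored),
                  side = 3, adj = 1, line = 0.2, cex = 0.9)
  invisible(path)
}

#' Behavioral raster figure across runs
#'
#' One row per run: trial marks at onset colored by trial type, response
#' marks at onset + response time colored by key, black ticks on correct
#' responses, vertical gridlines every 60 s, and a right margin listing
#' per-key counts, total responses, and accuracy — the same numbers stored
#' in each run's `behavior_result`.
#'
#' @param events_list list of [events_table()], one per run.
#' @param behavior_list list of matching `behavior_result`s (same order).
#' @param path output PNG path.
#' @param type_colors,key_colors named colors per trial type / response
#'   key; defaults follow the two-condition, two-key layout.
#' @return `path`, invisibly.
#' @export
behavior_figure <- function(events_list, behavior_list, path,
                            type_colors = c(CONTROL = "seagreen3",
                                            TASK = "goldenrod2"),
                            key_colors = c(LEFT = "royalblue",
                                           RIGHT = "firebrick")) {
  if (length(events_list) == 0L || length(events_list) != length(behavior_list))
    .stopf("events_list and behavior_list must be non-empty and the same length")
  ev_ids <- vapply(events_list, function(e) attr(e, "run_id"), character(1L))
  bh_ids <- vapply(behavior_list, function(b) b$run_id, character(1L))
  if (!identical(ev_ids, bh_ids))
    .stopf("events_list and behavior_list are not aligned by run_id")
  n_run <- length(events_list)
  tmax <- max(vapply(events_list, function(e) max(e$onset + e$duration),
                     numeric(1L)))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  grDevices::png(path, width = 1000, height = 120 + 60 * n_run)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(4, 7, 2, 14), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NA, xlim = c(0, tmax * 1.02), ylim = c(0.5, n_run + 0.5),
                 xlab = "time (s)", ylab = "", yaxt = "n",
                 main = "task presentation and responses")
  graphics::axis(2, at = seq_len(n_run), labels = rev(ev_ids), las = 1)
  graphics::abline(v = seq(0, tmax, by = 60), col = "grey80")
  for (i in seq_len(n_run)) {
    y <- n_run - i + 1L              # first run on top
    ev <- events_list[[i]]; bh <- behavior_list[[i]]
    tcol <- type_colors[ev$trial_type]; tcol[is.na(tcol)] <- "grey40"
    graphics::segments(ev$onset, y - 0.30, ev$onset, y - 0.05, col = tcol)
    resp <- !is.na(ev$response)
    if (any(resp)) {
      rt <- ev$onset[resp] + ev$response_time[resp]
      rcol <- key_colors[ev$response[resp]]; rcol[is.na(rcol)] <- "grey40"
      graphics::segments(rt, y + 0.05, rt, y + 0.30, col = rcol)
      ok <- resp & !is.na(ev$correct) & ev$correct
      if (any(ok))
        graphics::points(ev$onset[ok] + ev$response_time[ok],
                         rep(y + 0.38, sum(ok)), pch = "|", cex = 0.5)
    }
    keys <- bh$n_responses_by_key
    margin <- sprintf("%s  total %d  acc %s",
                      paste(sprintf("%s %d", names(keys), keys),
                            collapse = "  "),
                      bh$n_responses_total,
                      if (is.na(bh$accuracy_responded)) "n/a"
                      else sprintf("%.2f", bh$accuracy_responded))
    graphics::mtext(margin, side = 4, at = y, las = 1, line = 0.5, cex = 0.75)
  }
  invisible(path)
}

.embed_png <- function(path) {
  sprintf('<img src="data:image/png;base64,%s" style="max-width:100%%"/>',
          jsonlite::base64_enc(readBin(path, "raw", file.size(path))))
}

.html_page <- function(title, body, timestamp = FALSE) {
  stamp <- if (timestamp)
    sprintf("<p class='stamp'>generated %s</p>", format(Sys.time())) else ""
  sprintf(paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'/><title>%s</title>",
    "<style>body{font-family:sans-serif;max-width:1100px;margin:auto}",
    "table{border-collapse:collapse}td,th{border:1px solid #999;",
    "padding:4px 8px}.fail{color:#b00;font-weight:bold}",
    ".stamp{color:#777}</style></head><body><h1>%s</h1>%s%s</body></html>"),
    title, title, stamp, body)
}

#' Assemble the dataset-level QC reports and decision record
#'
#' Writes two self-contained HTML documents — an image/motion report
#' (criteria A and D evidence) and a behavioral report (criteria B and C)
#' — plus `qc_decisions.json`, a schema-versioned JSON array with one
#' decision object per run. Reruns on identical inputs are byte-identical
#' unless `timestamp = TRUE`.
#'
#' @param runs list of per-run records, each a list with elements
#'   `run_id`, `events`, `motion`, `censor`, `behavior` and optionally
#'   `summaries` (a [temporal_summaries()] result) and `tr_s`.
#' @param decisions list of [qc_decision()] objects covering every run.
#' @param out_dir output directory (created if needed).
#' @param mismatches optional [detect_metadata_mismatch()] result to list
#'   in the image report.
#' @param timestamp embed a generation timestamp in the HTML (default
#'   `FALSE`, keeping output deterministic).
#' @return Named list of the three output paths, invisibly. A console
#'   summary lists excluded runs and their triggering criteria.
#' @export
build_reports <- function(runs, decisions, out_dir,
                          mismatches = list(), timestamp = FALSE) {
  run_ids <- vapply(runs, function(r) r$run_id, character(1L))
  dec_ids <- vapply(decisions, function(d) d$run_id, character(1L))
  missing <- setdiff(run_ids, dec_ids)
  if (length(missing) > 0L)
    .stopf("no decision supplied for run(s): %s",
           paste(missing, collapse = ", "))
  for (r in runs) {
    for (part in c("events", "behavior"))
      if (is.null(r[[part]]))
        .stopf("run '%s' is missing its '%s' record", r$run_id, part)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)

  # ---- machine-readable decision record
  decisions <- decisions[match(run_ids, dec_ids)]
  json_path <- file.path(out_dir, "qc_decisions.json")
  jsonlite::write_json(
    list(schema = "taskfmriqc-decisions/1",
         decisions = lapply(decisions, .decision_record)),
    json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")

  # ---- image/motion report (criteria A and D)
  motion_html <- character()
  for (r in runs) {
    if (is.null(r$motion) || is.null(r$censor)) next
    p <- file.path(fig_dir, sprintf("%s_motion.png", r$run_id))
    motion_figure(r$motion, r$censor, r$events, p,
                  tr_s = if (is.null(r$tr_s)) 2 else r$tr_s)
    motion_html <- c(motion_html,
                     sprintf("<h2>%s</h2>", r$run_id), .embed_png(p))
    if (!is.null(r$summaries)) {
      row <- character()
      for (what in c("mean_vol", "sd_vol", "tsnr_vol")) {
        mp <- file.path(fig_dir, sprintf("%s_%s.png", r$run_id,
                                         sub("_vol$", "", what)))
        write_montage_png(montage(r$summaries[[what]],
                                  n_slices = min(6L, dim(r$summaries[[what]])[3L])),
                          mp, scale = 8L)
        row <- c(row, sprintf("<td>%s<br/><small>%s</small></td>",
                              .embed_png(mp), sub("_vol$", "", what)))
      }
      motion_html <- c(motion_html,
                       sprintf("<table><tr>%s</tr></table>",
                               paste(row, collapse = "")))
    }
  }
  mm_html <- if (length(mismatches) > 0L) {
    rows <- vapply(mismatches, function(m) {
      devs <- paste(vapply(m$deviants, function(d)
        sprintf("%s=%s", d$run_id, d$value), character(1L)), collapse = "; ")
      sprintf("<tr><td>%s</td><td>%s</td><td class='fail'>%s</td></tr>",
              m$field,
              if (isTRUE(m$no_consensus)) "(no consensus)" else m$majority_value,
              devs)
    }, character(1L))
    sprintf(paste0("<h2>Acquisition metadata mismatches</h2>",
                   "<table><tr><th>field</th><th>majority</th>",
                   "<th>deviant runs</th></tr>%s</table>"),
            paste(rows, collapse = ""))
  } else "<h2>Acquisition metadata</h2><p>All runs consistent.</p>"

  img_report <- file.path(out_dir, "fmriqc_report.html")
  writeLines(.html_page("fMRI QC report (motion and images)",
                        paste(c(mm_html, motion_html), collapse = "\n"),
                        timestamp),
             img_report)

  # ---- behavioral report (criteria B and C)
  ev_list <- lapply(runs, `[[`, "events")
  bh_list <- lapply(runs, `[[`, "behavior")
  bp <- file.path(fig_dir, "behavior_raster.png")
  behavior_figure(ev_list, bh_list, bp)
  dec_rows <- vapply(decisions, function(d) {
    cell <- function(v) if (v %in% c("fail", "fail_by_override"))
      sprintf("<td class='fail'>%s</td>", v) else sprintf("<td>%s</td>", v)
    sprintf("<tr><td>%s</td>%s%s%s%s<td>%s</td></tr>",
            d$run_id, cell(d$criterion_a), cell(d$criterion_b),
            cell(d$criterion_c), cell(d$criterion_d),
            if (d$excluded) "<span class='fail'>excluded</span>" else "included")
  }, character(1L))
  dec_table <- sprintf(paste0(
    "<h2>Decisions</h2><table><tr><th>run</th><th>A</th><th>B</th>",
    "<th>C</th><th>D</th><th>outcome</th></tr>%s</table>"),
    paste(dec_rows, collapse = ""))
  notes <- unlist(lapply(bh_list, function(b) {
    msgs <- character()
    if (b$flags$criterion_c_exclude)
      msgs <- c(msgs, sprintf(
        "%s: criterion C (longest no-response streak %d%s, no-response fraction %.1f%%%s)",
        b$run_id, b$longest_no_response_run,
        if (b$exclude_by_run) " — at/above streak threshold" else "",
        100 * b$frac_no_response,
        if (b$exclude_by_fraction) " — above fraction threshold" else ""))
    if (b$flags$criterion_b_exclude)
      msgs <- c(msgs, sprintf("%s: criterion B (usable fraction %.2f)",
                              b$run_id, b$usable_fraction))
    if (length(b$count_messages) > 0L)
      msgs <- c(msgs, sprintf("%s: %s", b$run_id, b$count_messages))
    if (b$flags$single_button)
      msgs <- c(msgs, sprintf("%s: only one response button used (review)",
                              b$run_id))
    msgs
  }))
  notes_html <- if (length(notes) > 0L)
    sprintf("<h2>Notifications</h2><ul>%s</ul>",
            paste(sprintf("<li>%s</li>", notes), collapse = ""))
  else "<h2>Notifications</h2><p>None.</p>"
  behav_report <- file.path(out_dir, "behav_report.html")
  writeLines(.html_page("Behavioral QC report",
                        paste(dec_table, notes_html, .embed_png(bp),
                              sep = "\n"), timestamp),
             behav_report)

  excl <- Filter(function(d) d$excluded, decisions)
  if (length(excl) > 0L) {
    for (d in excl) {
      trig <- c(A = d$criterion_a, B = d$criterion_b, C = d$criterion_c,
                D = d$criterion_d)
      trig <- names(trig)[trig %in% c("fail", "fail_by_override")]
      message(sprintf("excluded %s (criterion %s)", d$run_id,
                      paste(trig, collapse = ", ")))
    }
  } else message("no runs excluded")
  invisible(list(decisions_json = json_path,
                 fmriqc_report = img_report,
                 behav_report = behav_report))
}

#' Run the full QC pipeline over loaded runs
#'
#' Convenience orchestrator: computes censoring, behavioral screening and
#' (when images are present) temporal summaries plus the metadata
#' consistency check, derives decisions, and writes the reports.
#'
#' @param inputs list of per-run input lists with elements `events`
#'   ([events_table()]), `motion` ([motion_record()]) and optionally
#'   `image` ([run_image()]).
#' @param out_dir report output directory, or `NULL` to skip report files.
#' @param fd_threshold_mm,censor_frac criterion-A thresholds.
#' @param max_no_resp_run,max_no_resp_frac criterion-C thresholds.
#' @param expected_by_type optional expected per-type trial counts.
#' @param expected_total expected trial total for criterion B.
#' @param overrides named list of criterion-D overrides per run_id, each
#'   `list(criterion = "D", status = "fail", note = "...")`.
#' @return List with `runs` (enriched per-run records), `decisions`,
#'   `mismatches`, and `report_paths` (when `out_dir` given).
#' @export
run_qc <- function(inputs, out_dir = NULL,
                   fd_threshold_mm = 0.9, censor_frac = 0.20,
                   max_no_resp_run = 5L, max_no_resp_frac = 0.40,
                   expected_by_type = NULL, expected_total = NULL,
                   overrides = list()) {
  runs <- list()
  images <- list()
  for (inp in inputs) {
    ev <- inp$events
    rid <- attr(ev, "run_id")
    censor <- if (!is.null(inp$motion))
      censor_frames(inp$motion, threshold_mm = fd_threshold_mm,
                    frac_threshold = censor_frac)
    else NULL
    behavior <- evaluate_behavior(ev, expected_by_type = expected_by_type,
                                  expected_total = expected_total,
                                  max_run = max_no_resp_run,
                                  max_frac = max_no_resp_frac)
    summaries <- if (!is.null(inp$image)) temporal_summaries(inp$image)
    if (!is.null(inp$image)) images[[rid]] <- inp$image
    tr <- if (!is.null(inp$image) &&
              !is.null(inp$image$metadata$RepetitionTime))
      inp$image$metadata$RepetitionTime else 2
    runs[[rid]] <- list(run_id = rid, events = ev, motion = inp$motion,
                        censor = censor, behavior = behavior,
                        summaries = summaries, tr_s = tr)
  }
  mismatches <- if (length(images) >= 3L)
    detect_metadata_mismatch(unname(images)) else list()
  flagged <- unique(unlist(lapply(mismatches, function(m)
    vapply(m$deviants, `[[`, character(1L), "run_id"))))
  decisions <- lapply(runs, function(r)
    decide_run(r$censor, r$behavior,
               needs_review = r$run_id %in% flagged,
               override = overrides[[r$run_id]],
               run_id = r$run_id))
  report_paths <- if (!is.null(out_dir))
    build_reports(unname(runs), unname(decisions), out_dir,
                  mismatches = mismatches)
  else NULL
  list(runs = runs, decisions = decisions, mismatches = mismatches,
       report_paths = report_paths)
}
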