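# Three small synthetic runs reused across report tests: one clean, one
# with a planted 5-trial no-response block (criterion C), one clean.
report_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    specs <- list(
      "sub-001" = synth_spec(seed = 101, n_trials = 16, n_frames = 40),
      "sub-002" = synth_spec(seed = 102, n_trials = 16, n_frames = 40,
                             missing_pattern = list(kind = "block", k = 5,
                                                    start_index = 6)),
      "sub-003" = synth_spec(seed = 103, n_trials = 16, n_frames = 40,
                             spikes = list(list(frame = 20,
                                                magnitude_mm = 1.4))))
    inputs <- lapply(names(specs), function(id)
      list(events = synth_events(specs[[id]], run_id = id),
           motion = synth_motion(specs[[id]], run_id = id)))
    cache <<- inputs
    inputs
  }
})

test_that("decision invariants hold and criterion D needs a note to fail", {
  d <- qc_decision("r1", "pass", "pass", "pass", "pass")
  expect_false(d$excluded)
  expect_true(qc_decision("r1", criterion_c = "fail")$excluded)
  expect_false(qc_decision("r1", criterion_d = "needs_review")$excluded)
  expect_true(qc_decision("r1", criterion_d = "fail_by_override",
                          override_note = "wrong protocol")$excluded)
  expect_error(qc_decision("r1", criterion_d = "fail_by_override"),
               "override")
})

test_that("decide_run maps quantitative results onto criteria", {
  fd <- c(rep(0, 70), rep(1.2, 30))
  cen <- censor_frames(fd, run_id = "r")
  resp <- rep("LEFT", 16); resp[3:7] <- NA
  bh <- evaluate_behavior(make_events(resp, run_id = "r"))
  d <- decide_run(cen, bh)
  expect_identical(d$criterion_a, "fail")   # 30% censored
  expect_identical(d$criterion_c, "fail")   # 5-streak
  expect_identical(d$criterion_b, "pass")
  expect_true(d$excluded)
  d2 <- decide_run(NULL, NULL, needs_review = TRUE, run_id = "r")
  expect_identical(d2$criterion_d, "needs_review")
  expect_false(d2$excluded)
  d3 <- decide_run(NULL, NULL, run_id = "r",
                   override = list(criterion = "D", status = "fail",
                                   note = "acquired with wrong protocol"))
  expect_true(d3$excluded)
})

test_that("motion figure validates run identity and writes a file", {
  m <- synth_motion(synth_spec(seed = 55, n_frames = 30), run_id = "a")
  cen <- censor_frames(m)
  p <- tempfile(fileext = ".png")
  motion_figure(m, cen, path = p)
  expect_true(file.size(p) > 0)
  cen_b <- censor_frames(m$fd, run_id = "b")
  expect_error(motion_figure(m, cen_b, path = p), "different runs")
})

test_that("behavior figure requires aligned run lists", {
  inputs <- report_fixture()
  evs <- lapply(inputs, `[[`, "events")
  bhs <- lapply(evs, evaluate_behavior)
  p <- tempfile(fileext = ".png")
  behavior_figure(evs, bhs, p)
  expect_true(file.size(p) > 0)
  expect_error(behavior_figure(evs, rev(bhs), p), "aligned")
  expect_error(behavior_figure(list(), list(), p), "non-empty")
})

test_that("the pipeline excludes exactly the planted criterion-C run", {
  out <- tempfile("qc")
  res <- suppressMessages(run_qc(report_fixture(), out_dir = out))
  rec <- jsonlite::read_json(file.path(out, "qc_decisions.json"),
                             simplifyVector = FALSE)
  expect_identical(rec$schema, "taskfmriqc-decisions/1")
  dec <- rec$decisions
  excluded <- Filter(function(d) isTRUE(d$excluded), dec)
  expect_length(excluded, 1L)
  expect_identical(excluded[[1L]]$run_id, "sub-002")
  expect_identical(excluded[[1L]]$criterion_c, "fail")
  # a single 1.4 mm spike in 40 frames censors one frame but keeps the run
  sub3 <- Filter(function(d) d$run_id == "sub-003", dec)[[1L]]
  expect_identical(sub3$criterion_a, "pass")
  expect_equal(res$runs[["sub-003"]]$censor$n_censored, 1L)
  expect_true(file.exists(file.path(out, "fmriqc_report.html")))
  expect_true(file.exists(file.path(out, "behav_report.html")))
})

test_that("excluded can be re-derived from the JSON record alone", {
  out <- tempfile("qc")
  suppressMessages(run_qc(report_fixture(), out_dir = out))
  dec <- jsonlite::read_json(file.path(out, "qc_decisions.json"))$decisions
  for (d in dec) {
    rederived <- any(unlist(d[c("criterion_a", "criterion_b",
                                "criterion_c")]) == "fail") ||
      identical(d$criterion_d, "fail_by_override")
    expect_identical(d$excluded, rederived)
  }
})

test_that("reports are byte-identical across reruns on the same inputs", {
  out1 <- tempfile("qc"); out2 <- tempfile("qc")
  suppressMessages(run_qc(report_fixture(), out_dir = out1))
  suppressMessages(run_qc(report_fixture(), out_dir = out2))
  for (f in c("qc_decisions.json", "fmriqc_report.html",
              "behav_report.html")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("build_reports insists on a decision for every run", {
  inputs <- report_fixture()
  runs <- lapply(inputs, function(inp) {
    ev <- inp$events
    list(run_id = attr(ev, "run_id"), events = ev, motion = inp$motion,
         censor = censor_frames(inp$motion), behavior = evaluate_behavior(ev))
  })
  decs <- lapply(runs[1:2], function(r)
    decide_run(r$censor, r$behavior, run_id = r$run_id))
  expect_error(build_reports(runs, decs, tempfile()), "sub-003")
})

test_that("criterion-D override flows through the pipeline", {
  inputs <- report_fixture()
  res <- suppressMessages(run_qc(
    inputs, out_dir = NULL,
    overrides = list("sub-001" = list(criterion = "D", status = "fail",
                                      note = "distorted images on review"))))
  d1 <- res$decisions[["sub-001"]]
  expect_identical(d1$criterion_d, "fail_by_override")
  expect_true(d1$excluded)
  expect_identical(d1$override_note, "distorted images on review")
})
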