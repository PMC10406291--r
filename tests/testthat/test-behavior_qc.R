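test_that("trial counts are checked against the design", {
  ev <- make_events(rep("LEFT", 64),
                    trial_type = rep(c("CONTROL", "TASK"), each = 32))
  ok <- check_trial_counts(ev, c(CONTROL = 32, TASK = 32))
  expect_false(ok$counts_mismatch)
  expect_length(ok$messages, 0L)

  ev2 <- make_events(rep("LEFT", 63),
                     trial_type = c(rep("CONTROL", 31), rep("TASK", 32)))
  bad <- check_trial_counts(ev2, c(CONTROL = 32, TASK = 32))
  expect_true(bad$counts_mismatch)
  expect_match(bad$messages, "CONTROL", all = FALSE)

  ev3 <- make_events(rep("LEFT", 3),
                     trial_type = c("CONTROL", "TASK", "ODDBALL"))
  odd <- check_trial_counts(ev3, c(CONTROL = 1, TASK = 1))
  expect_true(odd$counts_mismatch)
  expect_match(odd$messages, "ODDBALL", all = FALSE)
})

test_that("criterion B is strict at half the expected trials", {
  ev64 <- make_events(rep("LEFT", 64))
  expect_false(evaluate_criterion_b(ev64, 64)$criterion_b_exclude)
  expect_equal(evaluate_criterion_b(ev64, 64)$usable_fraction, 1.0)
  expect_true(evaluate_criterion_b(ev64, 64,
                                   usable_trials = 31)$criterion_b_exclude)
  # exactly half is kept: the rule is "< 1/2", not "<= 1/2"
  expect_false(evaluate_criterion_b(ev64, 64,
                                    usable_trials = 32)$criterion_b_exclude)
  ev31 <- make_events(rep("LEFT", 31))
  expect_true(evaluate_criterion_b(ev31, 64)$criterion_b_exclude)
})

test_that("longest no-response streak is found", {
  ev <- make_events(c("L", NA, NA, NA, NA, NA, "L"))
  expect_equal(longest_no_response_run(ev), 5L)
  expect_equal(longest_no_response_run(make_events(rep("L", 10))), 0L)
})

test_that("streak detector matches the O(n^2) substring oracle", {
  set.seed(2024)
  for (rep in 1:200) {
    n <- sample(5:60, 1)
    miss <- runif(n) < runif(1, 0.1, 0.7)
    resp <- ifelse(miss, NA_character_, "LEFT")
    if (all(is.na(resp))) resp[1] <- "LEFT"  # keep at least one response
    ev <- make_events(resp)
    expect_identical(longest_no_response_run(ev),
                     oracle_longest_run(is.na(ev$response)))
  }
})

test_that("criterion C separates its streak and fraction components", {
  # 26/64 missing, scattered with max streak 2: fraction fires (0.406 > 0.40)
  resp <- rep("LEFT", 64)
  resp[c(seq(1, 37, by = 3), seq(40, 64, by = 2))] <- NA
  stopifnot(sum(is.na(resp)) == 26)
  ev <- make_events(resp)
  r <- evaluate_criterion_c(ev)
  expect_true(r$criterion_c_exclude)
  expect_true(r$exclude_by_fraction)
  expect_false(r$exclude_by_run)

  # 25/64 missing with max streak 4: both components below threshold
  resp2 <- rep("LEFT", 64)
  resp2[c(1:4, 8:11, 15:18, 22:25, 29:32, 36:39, 43)] <- NA
  stopifnot(sum(is.na(resp2)) == 25)
  r2 <- evaluate_criterion_c(make_events(resp2))
  expect_false(r2$criterion_c_exclude)
  expect_equal(r2$frac_no_response, 25 / 64)

  # 5 consecutive misses alone suffice (streak component only)
  resp3 <- rep("LEFT", 64); resp3[20:24] <- NA
  r3 <- evaluate_criterion_c(make_events(resp3))
  expect_true(r3$criterion_c_exclude)
  expect_true(r3$exclude_by_run)
  expect_false(r3$exclude_by_fraction)
})

test_that("the fraction component is permutation-invariant, the streak is not", {
  set.seed(5)
  resp <- c(rep(NA_character_, 6), rep("LEFT", 14))
  ev <- make_events(resp)
  r <- evaluate_criterion_c(ev)
  perm <- make_events(sample(resp))
  rp <- evaluate_criterion_c(perm)
  expect_equal(rp$frac_no_response, r$frac_no_response)
  expect_identical(rp$exclude_by_fraction, r$exclude_by_fraction)
  # the planted 6-streak fires; a scattered permutation need not
  expect_true(r$exclude_by_run)
})

test_that("response summary counts keys and computes responded-only accuracy", {
  ev <- make_events(c("LEFT", "RIGHT", NA),
                    correct = c(TRUE, FALSE, NA))
  rs <- response_summary(ev)
  expect_equal(rs$n_responses_by_key, c(LEFT = 1L, RIGHT = 1L))
  expect_equal(rs$n_responses_total, 2L)
  expect_equal(rs$accuracy_responded, 0.5)

  all_ok <- make_events(rep(c("LEFT", "RIGHT"), 32), correct = TRUE)
  rs2 <- response_summary(all_ok)
  expect_equal(rs2$n_responses_total, 64L)
  expect_equal(rs2$accuracy_responded, 1.0)
})

test_that("response totals match a one-pass counting oracle", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(10:80, 1)
    resp <- sample(c("LEFT", "RIGHT", NA), n, replace = TRUE)
    corr <- ifelse(is.na(resp), NA, runif(n) < 0.8)
    ev <- make_events(resp, correct = corr)
    rs <- response_summary(ev)
    expect_equal(rs$n_responses_total, sum(!is.na(resp)))
    expect_equal(rs$n_no_response, sum(is.na(resp)))
    for (key in names(rs$n_responses_by_key))
      expect_equal(rs$n_responses_by_key[[key]],
                   sum(resp == key, na.rm = TRUE))
    # exact complement identity
    expect_identical(rs$n_no_response + rs$n_responses_total, n)
  }
})

test_that("single-button responding is flagged only with enough evidence", {
  expect_true(detect_single_button(make_events(rep("LEFT", 40))))
  expect_false(detect_single_button(
    make_events(c(rep("LEFT", 39), "RIGHT"))))
  expect_false(detect_single_button(
    make_events(c(rep("LEFT", 5), rep(NA, 10)))))  # 5 < min_responses
})

test_that("evaluate_behavior assembles a coherent record", {
  resp <- rep(c("LEFT", "RIGHT"), 32); resp[10:14] <- NA
  ev <- make_events(resp, trial_type = rep(c("CONTROL", "TASK"), 32),
                    run_id = "sub-x")
  b <- evaluate_behavior(ev, expected_by_type = c(CONTROL = 32, TASK = 32))
  expect_s3_class(b, "behavior_result")
  expect_identical(b$run_id, "sub-x")
  expect_equal(b$n_responses_total + b$n_no_response, b$n_trials)
  expect_equal(b$frac_no_response + b$n_responses_total / b$n_trials, 1)
  expect_true(b$flags$criterion_c_exclude)     # planted 5-streak
  expect_false(b$flags$criterion_b_exclude)
  expect_false(b$flags$counts_mismatch)
  expect_false(b$flags$single_button)
})
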