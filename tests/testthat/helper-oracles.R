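# Independent brute-force oracles. These deliberately use naive loops so
# they share no code path with the implementation they check.

# Framewise displacement, frame by frame.
oracle_fd <- function(trans, rot, radius = 50) {
  n <- nrow(trans)
  fd <- numeric(n)
  for (t in seq_len(n)[-1L]) {
    s <- 0
    for (j in 1:3) s <- s + abs(trans[t, j] - trans[t - 1L, j])
    for (j in 1:3) s <- s + radius * abs(rot[t, j] - rot[t - 1L, j])
    fd[t] <- s
  }
  fd
}

# Longest all-missing streak by checking every contiguous substring: O(n^2).
oracle_longest_run <- function(miss) {
  n <- length(miss)
  best <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(miss[i:j]) && (j - i + 1L) > best) best <- j - i + 1L
    }
  }
  best
}

# Temporal summaries via an explicit per-voxel loop.
oracle_summaries <- function(arr) {
  d <- dim(arr)
  mean_vol <- array(0, d[1:3]); sd_vol <- array(0, d[1:3])
  tsnr_vol <- array(0, d[1:3])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    x <- arr[i, j, k, ]
    mean_vol[i, j, k] <- mean(x)
    sd_vol[i, j, k] <- stats::sd(x)
    tsnr_vol[i, j, k] <- if (stats::sd(x) > 0) mean(x) / stats::sd(x) else 0
  }
  list(mean = mean_vol, sd = sd_vol, tsnr = tsnr_vol)
}

# Trial/censor overlap by exhaustive interval membership.
oracle_overlap <- function(onset, duration, censored_times) {
  affected <- logical(length(onset))
  n_in <- 0L
  for (tm in censored_times) {
    inside <- FALSE
    for (i in seq_along(onset)) {
      if (tm >= onset[i] && tm < onset[i] + duration[i]) {
        affected[i] <- TRUE
        inside <- TRUE
      }
    }
    if (inside) n_in <- n_in + 1L
  }
  list(affected = affected, n_in = n_in,
       n_out = length(censored_times) - n_in)
}

# Compact events-table builder for behavioral tests: responses is a
# character vector with NA for no-response trials.
make_events <- function(responses, correct = NULL, run_id = "test",
                        trial_type = NULL, onset = NULL) {
  n <- length(responses)
  events_table(
    onset = if (is.null(onset)) seq(0, by = 8, length.out = n) else onset,
    duration = rep(2, n),
    trial_type = if (is.null(trial_type))
      rep(c("CONTROL", "TASK"), length.out = n) else trial_type,
    response = responses,
    response_time = ifelse(is.na(responses), NA_real_, 0.8),
    correct = if (is.null(correct)) ifelse(is.na(responses), NA, TRUE)
              else correct,
    run_id = run_id
  )
}
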