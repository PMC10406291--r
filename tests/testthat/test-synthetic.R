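test_that("generation is fully deterministic under a fixed seed", {
  spec <- synth_spec(seed = 20, n_trials = 16, n_frames = 30,
                     missing_pattern = list(kind = "scattered", k = 4),
                     spikes = list(list(frame = 10, magnitude_mm = 1.5)),
                     phantom = list(shape = c(6L, 6L, 4L)))
  expect_identical(synth_events(spec), synth_events(spec))
  m1 <- synth_motion(spec); m2 <- synth_motion(spec)
  expect_identical(m1$trans, m2$trans)
  expect_identical(m1$fd, m2$fd)
  b1 <- synth_bold(spec); b2 <- synth_bold(spec)
  expect_identical(b1$data, b2$data)
  # a different seed changes the draw
  expect_false(identical(synth_events(synth_spec(seed = 21, n_trials = 16)),
                         synth_events(synth_spec(seed = 20, n_trials = 16))))
  # the generators do not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(synth_events(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("events generator honours rate, proportions and RT model", {
  spec <- synth_spec(seed = 2, n_trials = 64)
  ev <- synth_events(spec)
  expect_equal(nrow(ev), 64L)
  expect_equal(unname(table(ev$trial_type)["CONTROL"]), 32,
               ignore_attr = TRUE)
  # ~7 trials/min: 64 trials span about 9 minutes
  expect_equal(max(ev$onset) / 60, 63 * (60 / 7) / 60, tolerance = 0.15)
  expect_true(all(ev$response_time > 0))
  expect_equal(stats::median(ev$response_time), 0.8, tolerance = 0.15)
})

test_that("planted missing patterns are recovered exactly", {
  blk <- synth_events(synth_spec(seed = 4, missing_pattern =
                                   list(kind = "block", k = 5,
                                        start_index = 10)))
  expect_identical(which(is.na(blk$response)), 10:14)
  expect_equal(longest_no_response_run(blk), 5L)

  none <- synth_events(synth_spec(seed = 4))
  bn <- evaluate_behavior(none)
  expect_equal(bn$n_responses_total, 64L)
  expect_false(bn$flags$criterion_c_exclude)

  sc <- synth_events(synth_spec(seed = 4, missing_pattern =
                                  list(kind = "scattered", k = 26)))
  expect_equal(sum(is.na(sc$response)), 26L)

  expect_error(synth_events(synth_spec(missing_pattern =
                                         list(kind = "scattered", k = 99))),
               "exceeds")
})

test_that("a decaying attention lapse triggers the fraction component", {
  ev <- synth_events(synth_spec(seed = 6, missing_pattern =
                                  list(kind = "decaying", rate = 4)))
  r <- evaluate_criterion_c(ev)
  expect_true(r$exclude_by_fraction)   # planted to exceed 40% missing
  # misses concentrate late in the run
  miss <- is.na(ev$response)
  expect_gt(mean(miss[33:64]), mean(miss[1:32]))
})

test_that("planted motion spikes are recovered exactly", {
  one <- synth_motion(synth_spec(seed = 9, n_frames = 100,
                                 spikes = list(list(frame = 50,
                                                    magnitude_mm = 1.2))))
  cen <- censor_frames(one, threshold_mm = 0.9)
  expect_identical(cen$censored_frame_indices, 50L)
  expect_equal(one$fd[50], 1.2, tolerance = 1e-12)

  still <- synth_motion(synth_spec(seed = 9, n_frames = 50, drift_mm = 0))
  expect_equal(still$fd, rep(0, 50))

  expect_error(synth_motion(synth_spec(n_frames = 20,
                                       spikes = list(list(frame = 30,
                                                          magnitude_mm = 1)))),
               "spike")
})

test_that("many planted spikes drive the run over the exclusion fraction", {
  spec <- synth_spec(seed = 13, n_frames = 100,
                     spikes = lapply(seq(4, 100, by = 4),
                                     function(f) list(frame = f,
                                                      magnitude_mm = 1.0)))
  m <- synth_motion(spec)
  cen <- censor_frames(m)
  expect_equal(cen$n_censored, 25L)
  expect_true(cen$exclude_run)   # 0.25 >= 0.20
})

test_that("the phantom realizes its tSNR target and zero background", {
  spec <- synth_spec(seed = 17, n_frames = 200,
                     phantom = list(tsnr_target = 50))
  img <- synth_bold(spec)
  s <- temporal_summaries(img)
  mask <- attr(img, "brain_mask")
  med <- stats::median(s$tsnr_vol[mask])
  expect_gte(med, 45); expect_lte(med, 55)
  expect_true(all(s$sd_vol[!mask] == 0))
  expect_gt(s$zero_sd_voxel_count, 0L)
  expect_error(synth_bold(synth_spec(phantom = list(tsnr_target = 0))),
               "tsnr_target")
})

test_that("a distorted phantom is caught by the metadata check", {
  specs <- lapply(1:6, function(i) synth_spec(seed = 30 + i, n_frames = 10,
                                              phantom = list(shape = c(8L, 8L, 4L))))
  runs <- Map(function(sp, i) synth_bold(sp, run_id = sprintf("sub-%03d", i)),
              specs, 1:6)
  runs[[3L]] <- synth_bold(
    synth_spec(seed = 33, n_frames = 10,
               phantom = list(shape = c(8L, 8L, 4L),
                              distortion = list(kind = "affine",
                                                shear = 0.5, scale = 1.4))),
    run_id = "sub-003")
  mm <- detect_metadata_mismatch(unname(runs))
  expect_gte(length(mm), 1L)
  flagged <- unique(unlist(lapply(mm, function(m)
    vapply(m$deviants, `[[`, "", "run_id"))))
  expect_identical(flagged, "sub-003")
  # distortion moves brain voxels relative to the undistorted mask
  base <- attr(synth_bold(specs[[3L]], run_id = "sub-003"), "brain_mask")
  expect_false(identical(attr(runs[[3L]], "brain_mask"), base))
})

test_that("synth_dataset writes a readable BIDS-like tree", {
  out <- tempfile("ds")
  specs <- list("sub-001" = synth_spec(seed = 41, n_trials = 8,
                                       n_frames = 6,
                                       phantom = list(shape = c(6L, 6L, 4L))),
                "sub-002" = synth_spec(seed = 42, n_trials = 8,
                                       n_frames = 6,
                                       phantom = list(shape = c(6L, 6L, 4L))))
  paths <- synth_dataset(specs, out, task = "demo")
  p1 <- paths[["sub-001"]]
  expect_true(all(file.exists(unlist(p1))))
  ev <- read_events(p1$events, run_id = "sub-001")
  expect_equal(nrow(ev), 8L)
  m <- read_confounds(p1$confounds)
  expect_identical(m$fd_source, "file")
  img <- read_run_image(p1$bold, p1$sidecar)
  expect_equal(img$shape, c(6L, 6L, 4L, 6L))
  expect_identical(img$metadata$TaskName, "synthetic")
})
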