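# Synthetic events, motion and phantom-image generators with planted ground
# truth, so every QC stage is testable without real data. Identical seed +
# spec give identical output; seeds are scoped with withr so the caller's
# RNG state is untouched.

#' Build a synthetic-run specification
#'
#' Collects every knob the three generators read, with defaults emulating
#' a rapid two-condition button-press task: 64 trials at about 7 per
#' minute, two response keys, lognormal response times (median 0.8 s,
#' sdlog 0.3).
#'
#' @param seed integer seed; the sole source of randomness.
#' @param n_trials number of trials (default 64).
#' @param trial_types named numeric vector of type proportions (default
#'   `c(CONTROL = 0.5, TASK = 0.5)`).
#' @param trial_rate_per_min average trial presentation rate (default 7).
#' @param trial_duration_s stimulus duration per trial, seconds.
#' @param response_keys labels of the two (or more) response keys.
#' @param missing_pattern no-response plan: `list(kind = "none")`,
#'   `list(kind = "scattered", k = )`, `list(kind = "block", k = ,
#'   start_index = )` (1-based first missing trial), or `list(kind =
#'   "decaying", rate = )` where the per-trial miss probability rises as
#'   `1 - exp(-rate * (i-1)/(n-1))`.
#' @param accuracy probability a responded trial is correct.
#' @param n_frames,tr_s imaging timebase for motion and BOLD.
#' @param spikes list of `list(frame = , magnitude_mm = )` motion spikes;
#'   realized as single-frame translation steps so the planted FD is
#'   exact.
#' @param drift_mm peak amplitude of the slow head-drift component.
#' @param phantom list: `shape` (3 ints), `brain_axes_vox` (ellipsoid
#'   semi-axes in voxels), `baseline` intensity, `tsnr_target`,
#'   `distortion` (`list(kind = "none")` or `list(kind = "affine",
#'   shear = , scale = )`), `voxel_size` (mm).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       n_trials = 64L,
                       trial_types = c(CONTROL = 0.5, TASK = 0.5),
                       trial_rate_per_min = 7,
                       trial_duration_s = 2,
                       response_keys = c("LEFT", "RIGHT"),
                       missing_pattern = list(kind = "none"),
                       accuracy = 0.95,
                       n_frames = 300L,
                       tr_s = 2,
                       spikes = list(),
                       drift_mm = 0.2,
                       phantom = list()) {
  ph_default <- list(shape = c(16L, 16L, 10L),
                     brain_axes_vox = c(6, 6, 4),
                     baseline = 1000,
                     tsnr_target = 50,
                     distortion = list(kind = "none"),
                     voxel_size = c(3, 3, 3))
  phantom <- utils::modifyList(ph_default, phantom)
  spec <- list(seed = as.integer(seed), n_trials = as.integer(n_trials),
               trial_types = trial_types,
               trial_rate_per_min = trial_rate_per_min,
               trial_duration_s = trial_duration_s,
               response_keys = response_keys,
               missing_pattern = missing_pattern,
               accuracy = accuracy,
               n_frames = as.integer(n_frames), tr_s = tr_s,
               spikes = spikes, drift_mm = drift_mm,
               phantom = phantom)
  class(spec) <- "synth_spec"
  spec
}

# Resolve a missing-response plan to a logical vector over trials.
.missing_mask <- function(pattern, n) {
  kind <- pattern$kind
  if (kind == "none") return(rep(FALSE, n))
  if (kind == "scattered") {
    k <- pattern$k
    if (k > n) .stopf("missing_pattern k (%d) exceeds n_trials (%d)", k, n)
    if (k == 0L) return(rep(FALSE, n))
    # spread misses so no two are adjacent where possible (max streak 1
    # for k <= ceiling(n/2)), keeping the fraction exact
    pos <- unique(round(seq(1, n, length.out = k)))
    extra <- setdiff(seq_len(n), pos)
    pos <- c(pos, extra[seq_len(k - length(pos))])
    mask <- rep(FALSE, n); mask[pos] <- TRUE
    mask
  } else if (kind == "block") {
    k <- pattern$k; s <- pattern$start_index
    if (k > n || s < 1L || s + k - 1L > n)
      .stopf("block(%d, %d) does not fit in %d trials", k, s, n)
    mask <- rep(FALSE, n); mask[s + seq_len(k) - 1L] <- TRUE
    mask
  } else if (kind == "decaying") {
    p <- 1 - exp(-pattern$rate * (seq_len(n) - 1L) / max(1L, n - 1L))
    stats::runif(n) < p
  } else .stopf("unknown missing_pattern kind '%s'", kind)
}

#' Generate a synthetic events table
#'
#' Onsets are spaced to achieve `trial_rate_per_min` with uniform jitter;
#' trial types follow the spec proportions in random order; response times
#' are lognormal (median 0.8 s, sdlog 0.3); the missing pattern is applied
#' exactly (except `decaying`, which is probabilistic by design);
#' correctness of responded trials is Bernoulli at the spec accuracy.
#'
#' @param spec a [synth_spec()].
#' @param run_id run identifier.
#' @param path optional path; when given the table is also written as a
#'   BIDS TSV via [write_events()].
#' @return An [events_table()].
#' @export
synth_events <- function(spec, run_id = "synth", path = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_trials
  withr::with_seed(spec$seed + 1L, {
    iti <- 60 / spec$trial_rate_per_min
    jitter <- stats::runif(n, -0.15 * iti, 0.15 * iti)
    onset <- (seq_len(n) - 1L) * iti + jitter - min(jitter)
    n_types <- round(n * spec$trial_types / sum(spec$trial_types))
    n_types[1L] <- n - sum(n_types[-1L])   # rounding residue to first type
    trial_type <- sample(rep(names(spec$trial_types), times = n_types))
    response <- sample(spec$response_keys, n, replace = TRUE)
    response_time <- stats::rlnorm(n, meanlog = log(0.8), sdlog = 0.3)
    correct <- stats::runif(n) < spec$accuracy
    miss <- .missing_mask(spec$missing_pattern, n)
    response[miss] <- NA_character_
    ev <- events_table(onset = onset,
                       duration = rep(spec$trial_duration_s, n),
                       trial_type = trial_type,
                       response = response,
                       response_time = response_time,
                       correct = correct,
                       run_id = run_id)
    if (!is.null(path)) write_events(ev, path)
    ev
  })
}

#' Generate a synthetic motion record
#'
#' Produces a smooth drift (cumulative Gaussian walk rescaled to peak
#' amplitude `drift_mm` for translations, `drift_mm / 50` radians for
#' rotations) plus the planted spikes. Each spike is a permanent
#' translation step of the stated magnitude on one axis, with the drift
#' increment zeroed at that frame, so the spike frame's FD equals the
#' planted magnitude exactly. Spike signs alternate so the trace stays
#' bounded.
#'
#' @param spec a [synth_spec()].
#' @param run_id run identifier.
#' @param path optional path; when given, a confounds TSV is written via
#'   [write_confounds()].
#' @return A [motion_record()] with `fd_source = "computed"`.
#' @export
synth_motion <- function(spec, run_id = "synth", path = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_frames
  if (n < 2L) .stopf("n_frames must be >= 2")
  spike_frames <- vapply(spec$spikes, function(s) as.integer(s$frame),
                         integer(1L))
  if (any(spike_frames < 2L | spike_frames > n))
    .stopf("spike frames must lie in [2, n_frames]")
  withr::with_seed(spec$seed + 2L, {
    walk <- function(scale) {
      inc <- stats::rnorm(n - 1L)
      inc[spike_frames - 1L] <- 0      # keep planted FD exact at spikes
      w <- c(0, cumsum(inc))
      if (max(abs(w)) > 0) w * scale / max(abs(w)) else w
    }
    # frame-to-frame drift steps shrink as 1/n; rescaling to peak drift_mm
    # keeps them far below any plausible censoring threshold
    trans <- vapply(1:3, function(i) walk(spec$drift_mm), numeric(n))
    rot <- vapply(1:3, function(i) walk(spec$drift_mm / 50), numeric(n))
    sgn <- 1
    for (s in spec$spikes) {
      f <- as.integer(s$frame)
      trans[f:n, 1L] <- trans[f:n, 1L] + sgn * s$magnitude_mm
      sgn <- -sgn
    }
    rec <- motion_record(trans, rot, run_id = run_id)
    if (!is.null(path)) write_confounds(rec, path)
    rec
  })
}

#' Generate a synthetic 4D BOLD phantom
#'
#' An ellipsoid "brain" at `baseline` intensity with i.i.d. Gaussian
#' temporal noise of sd `baseline / tsnr_target` inside the brain and
#' exactly zero signal outside, so the planted in-brain tSNR is the
#' target. Optional affine distortion (shear + scale of the ellipsoid
#' coordinates) emulates a mis-acquired run; when distortion is active the
#' sidecar is written with deviant `PhaseEncodingDirection` so the
#' metadata consistency check can catch it.
#'
#' @param spec a [synth_spec()].
#' @param run_id run identifier.
#' @param path optional `.nii.gz` path; when given the image and sidecar
#'   (`<stem>.json`) are written via [write_run_image()].
#' @return A [run_image()]. The ellipsoid mask is attached as attribute
#'   `"brain_mask"` for recovery statistics.
#' @export
synth_bold <- function(spec, run_id = "synth", path = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  ph <- spec$phantom
  if (ph$tsnr_target <= 0) .stopf("tsnr_target must be > 0")
  nt <- spec$n_frames
  if (nt < 2L) .stopf("n_frames must be >= 2")
  shape <- as.integer(ph$shape)
  ctr <- (shape + 1) / 2
  g <- expand.grid(x = seq_len(shape[1L]), y = seq_len(shape[2L]),
                   z = seq_len(shape[3L]))
  dx <- g$x - ctr[1L]; dy <- g$y - ctr[2L]; dz <- g$z - ctr[3L]
  if (ph$distortion$kind == "affine") {
    sc <- if (is.null(ph$distortion$scale)) 1 else ph$distortion$scale
    sh <- if (is.null(ph$distortion$shear)) 0 else ph$distortion$shear
    dx2 <- sc * dx + sh * dy
    dy2 <- dy / sc
    dx <- dx2; dy <- dy2
  } else if (ph$distortion$kind != "none") {
    .stopf("unknown distortion kind '%s'", ph$distortion$kind)
  }
  ax <- ph$brain_axes_vox
  mask <- (dx / ax[1L])^2 + (dy / ax[2L])^2 + (dz / ax[3L])^2 <= 1
  n_vox <- prod(shape)
  withr::with_seed(spec$seed + 3L, {
    data <- array(0, dim = c(shape, nt))
    noise_sd <- ph$baseline / ph$tsnr_target
    n_in <- sum(mask)
    m <- matrix(0, nrow = n_vox, ncol = nt)
    m[mask, ] <- ph$baseline +
      stats::rnorm(n_in * nt, sd = noise_sd)
    data[] <- m
    deviant <- ph$distortion$kind != "none"
    meta <- list(
      PhaseEncodingDirection = if (deviant) "i-" else "j-",
      RepetitionTime = spec$tr_s,
      TaskName = "synthetic")
    img <- run_image(data, voxel_size = ph$voxel_size, metadata = meta,
                     run_id = run_id)
    attr(img, "brain_mask") <- array(mask, dim = shape)
    if (!is.null(path)) {
      sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
      write_run_image(img, path, sidecar)
    }
    img
  })
}

#' Write a miniature BIDS-like synthetic dataset
#'
#' One directory `sub-XXX/func/` per run containing
#' `sub-XXX_task-<task>_events.tsv`, `_bold.nii.gz`, `_bold.json` and
#' `_desc-confounds_timeseries.tsv`.
#'
#' @param specs named list of [synth_spec()] objects, one per run; names
#'   are used as subject labels (e.g. `"sub-001"`).
#' @param out_dir output directory.
#' @param task task label used in file names.
#' @return Named list of per-run file paths, invisibly.
#' @export
synth_dataset <- function(specs, out_dir, task = "synth") {
  stopifnot(length(specs) > 0L, !is.null(names(specs)))
  out <- list()
  for (sub in names(specs)) {
    spec <- specs[[sub]]
    fdir <- file.path(out_dir, sub, "func")
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    stem <- file.path(fdir, sprintf("%s_task-%s", sub, task))
    paths <- list(
      events = paste0(stem, "_events.tsv"),
      bold = paste0(stem, "_bold.nii.gz"),
      sidecar = paste0(stem, "_bold.json"),
      confounds = paste0(stem, "_desc-confounds_timeseries.tsv"))
    synth_events(spec, run_id = sub, path = paths$events)
    synth_motion(spec, run_id = sub, path = paths$confounds)
    synth_bold(spec, run_id = sub, path = paths$bold)
    out[[sub]] <- paths
  }
  invisible(out)
}
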