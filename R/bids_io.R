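# BIDS-style per-run input artifacts: events TSV, confounds TSV, 4D NIfTI
# image + JSON sidecar. All readers normalize "n/a"/"NA"/"" to NA on load.

#' Construct an events table
#'
#' A per-trial record of task presentation and responses for one run.
#' Trials are sorted ascending by onset; a trial with a missing response
#' also has its response time set missing (no-response normalization).
#'
#' @param onset trial onset times, seconds from the first retained frame;
#'   finite and non-negative.
#' @param duration trial durations in seconds.
#' @param trial_type condition label per trial (e.g. `"CONTROL"`/`"TASK"`).
#' @param response response key per trial (e.g. `"LEFT"`/`"RIGHT"`), `NA`
#'   for no-response trials.
#' @param response_time response latency in seconds, `NA` when no response
#'   was recorded; must be positive where present.
#' @param correct logical correctness per trial, `NA` where unknown or no
#'   response was made.
#' @param run_id identifier for the run the table belongs to.
#' @return An object of class `events_table` (a `data.frame` with columns
#'   `onset`, `duration`, `trial_type`, `response`, `response_time`,
#'   `correct` and a `run_id` attribute).
#' @export
events_table <- function(onset, duration, trial_type,
                         response = NA_character_,
                         response_time = NA_real_,
                         correct = NA,
                         run_id = "run") {
  n <- length(onset)
  if (n == 0L) .stopf("events table must contain at least one trial")
  df <- data.frame(
    onset = as.numeric(onset),
    duration = as.numeric(duration),
    trial_type = as.character(trial_type),
    response = rep_len(as.character(response), n),
    response_time = rep_len(as.numeric(response_time), n),
    correct = rep_len(as.logical(correct), n),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(df$onset)) || any(df$onset < 0))
    .stopf("onsets must be finite and >= 0")
  if (any(!is.na(df$response_time) & df$response_time <= 0))
    .stopf("response_time must be > 0 where present")
  # no-response normalization: missing response implies missing RT/correct
  no_resp <- is.na(df$response)
  df$response_time[no_resp] <- NA_real_
  df$correct[no_resp] <- NA
  df <- df[order(df$onset), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, run_id = as.character(run_id),
            class = c("events_table", "data.frame"))
}

#' @export
print.events_table <- function(x, ...) {
  cat(sprintf("<events_table> run '%s': %d trials\n",
              attr(x, "run_id"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more trials\n", nrow(x) - 10L))
  invisible(x)
}

#' Read a BIDS events.tsv file
#'
#' Loads a tab-separated trial table. Cells equal to `"n/a"`, `"NA"` or
#' empty are treated as missing; rows are returned sorted by onset and
#' never dropped.
#'
#' @param path path to the `_events.tsv` file.
#' @param column_map optional named character vector mapping canonical
#'   column names to the names used in the file, e.g.
#'   `c(response_time = "reaction_time")`.
#' @param run_id run identifier; defaults to the file name without suffix.
#' @return An [events_table()].
#' @export
read_events <- function(path, column_map = NULL, run_id = NULL) {
  if (!file.exists(path)) .stopf("events file not found: '%s'", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  pick <- function(canonical, alternates = character()) {
    candidates <- c(if (!is.null(column_map) && canonical %in% names(column_map))
                      column_map[[canonical]],
                    canonical, alternates)
    hit <- candidates[candidates %in% names(raw)]
    if (length(hit) == 0L) NULL else raw[[hit[1L]]]
  }
  onset <- pick("onset")
  trial_type <- pick("trial_type")
  for (req in c("onset", "trial_type")) {
    if (is.null(get(req)))
      .stopf("events file '%s' lacks required column '%s'", path, req)
  }
  n <- nrow(raw)
  duration <- pick("duration")
  response <- pick("response")
  response_time <- pick("response_time", "reaction_time")
  correct <- pick("correct", c("correctness", "accuracy"))
  events_table(
    onset = .parse_numeric_column(onset, "onset", path),
    duration = if (is.null(duration)) rep(0, n)
               else .parse_numeric_column(duration, "duration", path),
    trial_type = ifelse(.is_missing_token(trial_type), NA, trial_type),
    response = if (is.null(response)) rep(NA_character_, n)
               else ifelse(.is_missing_token(response), NA, response),
    response_time = if (is.null(response_time)) rep(NA_real_, n)
                    else .parse_numeric_column(response_time,
                                               "response_time", path),
    correct = if (is.null(correct)) rep(NA, n)
              else .parse_logical_column(correct, "correct"),
    run_id = if (is.null(run_id))
               sub("_events$", "", tools::file_path_sans_ext(basename(path)))
             else run_id
  )
}

#' Write an events table as a BIDS TSV
#'
#' Missing cells are written as `"n/a"` (BIDS convention). Re-reading the
#' file with [read_events()] reproduces the table.
#'
#' @param events an [events_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "events_table"))
  cols <- lapply(as.data.frame(events), .format_bids_cell)
  out <- do.call(cbind, cols)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# ---- motion record ----------------------------------------------------------

#' Construct a motion record
#'
#' Per-frame rigid-body realignment parameters plus framewise displacement
#' (FD) for one run. Translations are in millimetres, rotations in radians
#' (fMRIPrep convention); this is documented, not auto-detected.
#'
#' @param trans n-by-3 matrix of translations (`trans_x/y/z`), mm.
#' @param rot n-by-3 matrix of rotations (`rot_x/y/z`), radians.
#' @param fd optional per-frame FD series in mm; computed with
#'   [compute_fd()] when absent. `fd[1]` must be 0 and all values
#'   non-negative.
#' @param run_id run identifier.
#' @param fd_source `"file"` if FD came from a confounds file, `"computed"`
#'   otherwise; set automatically by the readers.
#' @param head_radius_mm sphere radius used when FD must be computed.
#' @return An object of class `motion_record`: a list with elements
#'   `run_id`, `n_frames`, `trans`, `rot`, `fd`, `fd_source`.
#' @export
motion_record <- function(trans, rot, fd = NULL, run_id = "run",
                          fd_source = if (is.null(fd)) "computed" else "file",
                          head_radius_mm = 50) {
  trans <- as.matrix(trans); rot <- as.matrix(rot)
  if (ncol(trans) != 3L || ncol(rot) != 3L)
    .stopf("trans and rot must each have 3 columns")
  n <- nrow(trans)
  if (n < 1L || nrow(rot) != n)
    .stopf("trans and rot must have the same positive number of rows")
  if (any(!is.finite(trans)) || any(!is.finite(rot)))
    .stopf("motion parameters must be finite")
  rec <- structure(
    list(run_id = as.character(run_id), n_frames = n,
         trans = unname(trans), rot = unname(rot),
         fd = NULL, fd_source = fd_source),
    class = "motion_record")
  if (is.null(fd)) {
    rec$fd <- compute_fd(rec, head_radius_mm = head_radius_mm)
    rec$fd_source <- "computed"
  } else {
    fd <- as.numeric(fd)
    if (length(fd) != n) .stopf("fd must have one value per frame")
    if (any(!is.finite(fd)) || any(fd < 0))
      .stopf("fd values must be finite and >= 0")
    if (fd[1L] != 0) .stopf("fd[1] must be 0 (first frame has no predecessor)")
    rec$fd <- fd
  }
  rec
}

#' @export
print.motion_record <- function(x, ...) {
  cat(sprintf("<motion_record> run '%s': %d frames, FD %s (max %.3f mm)\n",
              x$run_id, x$n_frames, x$fd_source, max(x$fd)))
  invisible(x)
}

#' Read an fMRIPrep-style confounds timeseries TSV
#'
#' Requires the six realignment columns `trans_x`, `trans_y`, `trans_z`,
#' `rot_x`, `rot_y`, `rot_z`. If the FD column is present its first-row
#' `"n/a"` is replaced by 0 and `fd_source` is `"file"`; otherwise FD is
#' computed from the parameters and `fd_source` is `"computed"`.
#'
#' @param path path to the `_desc-confounds_timeseries.tsv` file.
#' @param fd_column name of the framewise-displacement column.
#' @param run_id run identifier; defaults to the file name without suffix.
#' @param head_radius_mm sphere radius (mm) used if FD must be computed.
#' @return A [motion_record()].
#' @export
read_confounds <- function(path, fd_column = "framewise_displacement",
                           run_id = NULL, head_radius_mm = 50) {
  if (!file.exists(path)) .stopf("confounds file not found: '%s'", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  absent <- setdiff(need, names(raw))
  if (length(absent) > 0L)
    .stopf("confounds file '%s' lacks motion column(s): %s",
           path, paste(absent, collapse = ", "))
  par <- vapply(need, function(cl) .parse_numeric_column(raw[[cl]], cl, path),
                numeric(nrow(raw)))
  par <- matrix(par, nrow = nrow(raw), ncol = 6L)
  if (any(is.na(par))) .stopf("motion parameters in '%s' contain missing values", path)
  rid <- if (is.null(run_id))
    sub("_desc-confounds.*$", "", tools::file_path_sans_ext(basename(path)))
  else run_id
  if (fd_column %in% names(raw)) {
    fd <- .parse_numeric_column(raw[[fd_column]], fd_column, path)
    if (is.na(fd[1L])) fd[1L] <- 0   # first frame has no predecessor
    if (any(is.na(fd)))
      .stopf("missing FD value after the first row in '%s'", path)
    if (any(fd < 0)) .stopf("negative FD value in '%s'", path)
    motion_record(par[, 1:3], par[, 4:6], fd = fd, run_id = rid,
                  fd_source = "file")
  } else {
    motion_record(par[, 1:3], par[, 4:6], run_id = rid,
                  head_radius_mm = head_radius_mm)
  }
}

#' Write a motion record as a confounds TSV
#'
#' Columns `trans_x..rot_z` plus `framewise_displacement` with the BIDS
#' first-row `"n/a"`.
#'
#' @param motion a [motion_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_confounds <- function(motion, path) {
  stopifnot(inherits(motion, "motion_record"))
  df <- data.frame(motion$trans, motion$rot, motion$fd)
  names(df) <- c("trans_x", "trans_y", "trans_z",
                 "rot_x", "rot_y", "rot_z", "framewise_displacement")
  out <- vapply(df, function(cl) .format_bids_cell(cl, digits = 10L),
                character(nrow(df)))
  out <- matrix(out, nrow = nrow(df), dimnames = list(NULL, names(df)))
  out[1L, "framewise_displacement"] <- "n/a"
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# ---- run image --------------------------------------------------------------

#' Construct a run image
#'
#' A preprocessed 4D BOLD series plus its JSON sidecar metadata.
#'
#' @param data 4D numeric array (x, y, z, t) with at least 2 timepoints.
#' @param voxel_size 3-vector of voxel dimensions, mm.
#' @param metadata named list from the JSON sidecar (typically includes
#'   `PhaseEncodingDirection` and `RepetitionTime`).
#' @param run_id run identifier.
#' @return An object of class `run_image`: list with `run_id`, `data`,
#'   `voxel_size`, `shape`, `metadata`.
#' @export
run_image <- function(data, voxel_size = c(1, 1, 1), metadata = list(),
                      run_id = "run") {
  if (length(dim(data)) != 4L)
    .stopf("image must be 4D (x, y, z, t); got %d dimension(s)",
           length(dim(data)))
  if (dim(data)[4L] < 2L)
    .stopf("image must have at least 2 timepoints (temporal sd undefined)")
  structure(list(run_id = as.character(run_id),
                 data = data,
                 voxel_size = as.numeric(voxel_size)[1:3],
                 shape = as.integer(dim(data)),
                 metadata = as.list(metadata)),
            class = "run_image")
}

#' @export
print.run_image <- function(x, ...) {
  cat(sprintf("<run_image> run '%s': %s voxels x %d frames, voxel %s mm\n",
              x$run_id, paste(x$shape[1:3], collapse = "x"), x$shape[4L],
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

#' Read a 4D NIfTI run with optional JSON sidecar
#'
#' @param image_path path to a `.nii` or `.nii.gz` 4D image.
#' @param sidecar_path optional path to the JSON sidecar; when absent (or
#'   `NULL`) the metadata map is empty. When `NULL`, a file with the same
#'   stem and a `.json` extension is used if it exists.
#' @param run_id run identifier; defaults to the file name without suffix.
#' @return A [run_image()].
#' @export
read_run_image <- function(image_path, sidecar_path = NULL, run_id = NULL) {
  if (!file.exists(image_path)) .stopf("image not found: '%s'", image_path)
  img <- RNifti::readNifti(image_path)
  dims <- dim(img)
  if (length(dims) != 4L)
    .stopf("'%s' is %dD; a 4D (x, y, z, t) image is required",
           image_path, length(dims))
  pd <- RNifti::pixdim(img)
  if (is.null(sidecar_path)) {
    guess <- paste0(sub("\\.nii(\\.gz)?$", "", image_path), ".json")
    if (file.exists(guess)) sidecar_path <- guess
  }
  meta <- if (!is.null(sidecar_path) && file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  else list()
  run_image(array(as.numeric(img), dim = dims),
            voxel_size = pd[1:3], metadata = meta,
            run_id = if (is.null(run_id))
              sub("_bold$", "",
                  sub("\\.nii(\\.gz)?$", "", basename(image_path)))
            else run_id)
}

#' Write a run image as NIfTI plus JSON sidecar
#'
#' @param image a [run_image()].
#' @param image_path output `.nii`/`.nii.gz` path.
#' @param sidecar_path output JSON path, or `NULL` to skip the sidecar.
#' @return `image_path`, invisibly.
#' @export
write_run_image <- function(image, image_path, sidecar_path = NULL) {
  stopifnot(inherits(image, "run_image"))
  dir.create(dirname(image_path), recursive = TRUE, showWarnings = FALSE)
  nii <- RNifti::asNifti(image$data)
  tr <- image$metadata$RepetitionTime
  RNifti::pixdim(nii) <- c(image$voxel_size,
                           if (is.null(tr)) 1 else as.numeric(tr))
  RNifti::writeNifti(nii, image_path)
  if (!is.null(sidecar_path) && length(image$metadata) > 0L)
    jsonlite::write_json(image$metadata, sidecar_path,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(image_path)
}
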