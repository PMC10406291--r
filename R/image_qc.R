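# Criterion D support: voxelwise temporal mean, sd and tSNR volumes,
# review montages, and acquisition-metadata consistency checks. Criterion D
# itself stays a qualitative human decision; this module only produces the
# evidence.

#' Voxelwise temporal summary volumes
#'
#' Computes the temporal mean, standard deviation and tSNR (mean/sd) of a
#' 4D run, per voxel, over the entire run without censoring — censoring is
#' deliberately not applied here so that between-run differences are
#' visually exaggerated during review. The sd uses the sample (n-1)
#' denominator by default. Voxels with zero temporal sd get tSNR 0 (not
#' Inf/NaN, so montages render) and are counted in
#' `zero_sd_voxel_count`.
#'
#' @param image a [run_image()] or a 4D numeric array.
#' @param sd_denominator `"n-1"` (sample, default) or `"n"` (population),
#'   for cross-checking against other toolchains.
#' @return An object of class `volume_summaries`: list with `run_id`,
#'   `mean_vol`, `sd_vol`, `tsnr_vol` (3D arrays of the input's spatial
#'   shape), `n_frames_used`, `zero_sd_voxel_count`.
#' @export
temporal_summaries <- function(image, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  run_id <- "run"
  if (inherits(image, "run_image")) {
    run_id <- image$run_id
    image <- image$data
  }
  d <- dim(image)
  if (length(d) != 4L) .stopf("image must be 4D (x, y, z, t)")
  nt <- d[4L]
  if (nt < 2L) .stopf("at least 2 timepoints required for temporal sd")
  m <- matrix(image, ncol = nt)          # voxels x time
  mu <- rowMeans(m)
  ss <- rowSums((m - mu)^2)
  denom <- if (sd_denominator == "n-1") nt - 1L else nt
  sdv <- sqrt(ss / denom)
  tsnr <- ifelse(sdv > 0, mu / sdv, 0)
  sp <- d[1:3]
  structure(
    list(run_id = run_id,
         mean_vol = array(mu, dim = sp),
         sd_vol = array(sdv, dim = sp),
         tsnr_vol = array(tsnr, dim = sp),
         n_frames_used = nt,
         zero_sd_voxel_count = sum(sdv == 0)),
    class = "volume_summaries")
}

#' @export
print.volume_summaries <- function(x, ...) {
  cat(sprintf(
    "<volume_summaries> run '%s': %s voxels over %d frames; %d zero-sd voxel(s)\n",
    x$run_id, paste(dim(x$mean_vol), collapse = "x"), x$n_frames_used,
    x$zero_sd_voxel_count))
  invisible(x)
}

#' Write summary volumes as NIfTI files
#'
#' Writes `<prefix>_mean.nii.gz`, `<prefix>_sd.nii.gz` and
#' `<prefix>_tsnr.nii.gz`.
#'
#' @param summaries a [temporal_summaries()] result.
#' @param prefix output path prefix (directory + file stem).
#' @param voxel_size 3-vector of voxel dimensions, mm.
#' @return Character vector of the three paths, invisibly.
#' @export
write_summaries <- function(summaries, prefix, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(summaries, "volume_summaries"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- character(3)
  vols <- list(mean = summaries$mean_vol, sd = summaries$sd_vol,
               tsnr = summaries$tsnr_vol)
  for (i in seq_along(vols)) {
    nii <- RNifti::asNifti(vols[[i]])
    RNifti::pixdim(nii) <- voxel_size
    paths[i] <- sprintf("%s_%s.nii.gz", prefix, names(vols)[i])
    RNifti::writeNifti(nii, paths[i])
  }
  invisible(paths)
}

#' Tile evenly spaced slices of a volume into a review montage
#'
#' Slices are taken evenly spaced along the chosen axis after excluding the
#' first and last 10\% (mostly-empty edge slices). Intensities are
#' windowed to `[0, 98th percentile of in-volume nonzero values]` and
#' scaled to `[0, 1]`; an all-zero volume yields an all-zero montage
#' without numeric warnings. Slices are laid out row-major in neurological
#' convention (subject left on viewer left).
#'
#' @param volume 3D numeric array.
#' @param n_slices number of slices to show (must not exceed the eligible
#'   extent of the axis).
#' @param axis `"axial"` (slices along z, default), `"coronal"` (y) or
#'   `"sagittal"` (x).
#' @param ncol_tiles tiles per montage row; default `ceiling(sqrt(n))`.
#' @return An object of class `qc_montage`: list with `image` (2D matrix
#'   in `[0, 1]`, rows = montage y), `slice_indices` (strictly
#'   increasing), `axis`, `window` (the intensity window used).
#' @export
montage <- function(volume, n_slices = 6L,
                    axis = c("axial", "coronal", "sagittal"),
                    ncol_tiles = NULL) {
  axis <- match.arg(axis)
  if (length(dim(volume)) != 3L) .stopf("volume must be a 3D array")
  if (n_slices < 1L) .stopf("n_slices must be >= 1")
  dim_index <- c(axial = 3L, coronal = 2L, sagittal = 1L)[[axis]]
  extent <- dim(volume)[dim_index]
  trim <- floor(0.10 * extent)
  lo <- trim + 1L; hi <- extent - trim
  eligible <- hi - lo + 1L
  if (n_slices > eligible)
    .stopf("n_slices (%d) exceeds the eligible axis extent (%d)",
           n_slices, eligible)
  idx <- unique(as.integer(round(seq(lo, hi, length.out = n_slices))))
  # rounding can collide for dense requests; fall back to exact coverage
  if (length(idx) < n_slices) idx <- seq.int(lo, hi)[seq_len(n_slices)]
  nz <- volume[volume != 0]
  upper <- if (length(nz) == 0L) 1 else
    as.numeric(stats::quantile(nz, 0.98, names = FALSE))
  if (upper <= 0) upper <- 1
  slice_of <- function(k) {
    s <- switch(axis,
                axial = volume[, , k],
                coronal = volume[, k, ],
                sagittal = volume[k, , ])
    pmin(pmax(s / upper, 0), 1)
  }
  tiles <- lapply(idx, slice_of)
  tw <- nrow(tiles[[1L]]); th <- ncol(tiles[[1L]])
  if (is.null(ncol_tiles)) ncol_tiles <- ceiling(sqrt(length(idx)))
  nrow_tiles <- ceiling(length(idx) / ncol_tiles)
  img <- matrix(0, nrow = nrow_tiles * th, ncol = ncol_tiles * tw)
  for (i in seq_along(tiles)) {
    r <- (i - 1L) %/% ncol_tiles; cc <- (i - 1L) %% ncol_tiles
    # transpose + reverse rows: array (x, y) -> raster (row = top of image)
    t_img <- t(tiles[[i]])[rev(seq_len(th)), , drop = FALSE]
    img[r * th + seq_len(th), cc * tw + seq_len(tw)] <- t_img
  }
  structure(list(image = img, slice_indices = idx, axis = axis,
                 window = c(0, upper)),
            class = "qc_montage")
}

#' Write a montage as a grayscale PNG
#'
#' @param m a [montage()] result.
#' @param path output PNG path.
#' @param scale integer pixel-replication factor for small phantoms.
#' @return `path`, invisibly.
#' @export
write_montage_png <- function(m, path, scale = 1L) {
  stopifnot(inherits(m, "qc_montage"))
  img <- m$image
  if (scale > 1L) {
    img <- img[rep(seq_len(nrow(img)), each = scale),
               rep(seq_len(ncol(img)), each = scale), drop = FALSE]
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(img, path)
  invisible(path)
}

#' Flag runs whose acquisition metadata deviates from the dataset majority
#'
#' For each checked field (JSON sidecar keys plus spatial shape and voxel
#' size) the modal value across runs is taken as the dataset majority; any
#' run differing from it is listed. When no majority exists the field is
#' reported as a "no consensus" mismatch. This is a review flag feeding
#' criterion D, never an automatic exclusion.
#'
#' @param runs list of [run_image()] objects (at least 3; a majority is
#'   undefined otherwise).
#' @param fields sidecar metadata keys to compare (default
#'   `PhaseEncodingDirection`, `RepetitionTime`). Spatial shape and voxel
#'   size are always compared.
#' @return List of `metadata_mismatch` entries, each with `field`,
#'   `majority_value`, `no_consensus` and `deviants` (list of
#'   `run_id`/`value`); empty when all runs agree.
#' @export
detect_metadata_mismatch <- function(runs,
                                     fields = c("PhaseEncodingDirection",
                                                "RepetitionTime")) {
  if (length(runs) < 3L)
    .stopf("at least 3 runs are required to define a majority")
  stopifnot(all(vapply(runs, inherits, logical(1L), "run_image")))
  ids <- vapply(runs, function(r) r$run_id, character(1L))
  value_of <- function(run, field) {
    v <- switch(field,
                "spatial_shape" = paste(run$shape[1:3], collapse = "x"),
                "voxel_size" = paste(signif(run$voxel_size, 6),
                                     collapse = "x"),
                run$metadata[[field]])
    if (is.null(v)) "<absent>" else paste(format(v), collapse = ",")
  }
  out <- list()
  for (field in c(fields, "spatial_shape", "voxel_size")) {
    vals <- vapply(runs, value_of, character(1L), field = field)
    if (all(vals == "<absent>")) next
    mode <- .modal_value(vals)
    if (mode$tied) {
      out[[length(out) + 1L]] <- structure(
        list(field = field, majority_value = NA_character_,
             no_consensus = TRUE,
             deviants = unname(Map(function(id, v)
               list(run_id = id, value = v), ids, vals))),
        class = "metadata_mismatch")
    } else if (any(vals != mode$value)) {
      dev <- which(vals != mode$value)
      out[[length(out) + 1L]] <- structure(
        list(field = field, majority_value = mode$value,
             no_consensus = FALSE,
             deviants = unname(Map(function(id, v)
               list(run_id = id, value = v), ids[dev], vals[dev]))),
        class = "metadata_mismatch")
    }
  }
  out
}
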