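#' Motor-network ROI definitions
#'
#' The five 6-mm-radius sphere ROIs of the motor-execution network, at
#' their published MNI centers (mm).
#'
#' @return Tibble with columns `name`, `x`, `y`, `z`, `radius`.
#' @export
motor_rois <- function() {
  tibble(
    name = c("LM1", "RM1", "LPMC", "RPMC", "SMA"),
    x = c(-33.0, 35.7, -34.3, 35.1, 0.0),
    y = c(-19.8, -18.1, -1.4, 0.1, -4.2),
    z = c(52.1, 52.0, 55.8, 54.9, 64.7),
    radius = 6
  )
}

as_roi_row <- function(roi) {
  if (is.data.frame(roi)) {
    stopifnot(nrow(roi) == 1)
    roi <- as.list(roi)
  }
  if (is.null(roi$radius)) roi$radius <- 6
  stopifnot(all(c("name", "x", "y", "z") %in% names(roi)))
  if (roi$radius <= 0) abort("ROI radius must be > 0")
  roi
}

#' Sphere ROI voxel mask
#'
#' Marks every voxel whose center (the voxel index mapped through the image
#' affine, 0-based indices) lies within `radius` mm of the ROI center
#' (closed ball, millimeter world space).
#'
#' @param roi one-row data frame (or list) with `name`, `x`, `y`, `z`,
#'   `radius` in mm.
#' @param affine invertible 4 x 4 voxel-to-mm matrix.
#' @param grid_shape integer 3-vector of grid dimensions.
#' @return Logical array of dimension `grid_shape`.
#' @export
sphere_mask <- function(roi, affine, grid_shape) {
  roi <- as_roi_row(roi)
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4, 4)), length(grid_shape) == 3,
            all(grid_shape > 0))
  if (abs(det(affine)) < 1e-12) abort("affine must be invertible")
  center <- c(roi$x, roi$y, roi$z)

  idx <- as.matrix(expand.grid(
    i = seq_len(grid_shape[1]) - 1L,
    j = seq_len(grid_shape[2]) - 1L,
    k = seq_len(grid_shape[3]) - 1L
  ))
  world <- cbind(idx, 1) %*% t(affine)
  d2 <- (world[, 1] - center[1])^2 + (world[, 2] - center[2])^2 +
    (world[, 3] - center[3])^2
  mask <- array(d2 <= roi$radius^2, dim = grid_shape)

  if (!any(mask)) {
    lo <- apply(world[, 1:3, drop = FALSE], 2, min) - roi$radius
    hi <- apply(world[, 1:3, drop = FALSE], 2, max) + roi$radius
    if (any(center < lo) || any(center > hi)) {
      abort(sprintf(
        "ROI %s: center (%.1f, %.1f, %.1f) lies outside the grid by more than its radius",
        roi$name, center[1], center[2], center[3]
      ))
    }
    abort(sprintf("ROI %s: no voxel centers within radius %.2f mm",
                  roi$name, roi$radius))
  }
  mask
}

#' Extract mean ROI time series from a 4D volume
#'
#' Per ROI and volume, the unweighted mean over the sphere-mask voxels.
#' Column order follows the input ROI list.
#'
#' @param volume4d path to a NIfTI file, an `RNifti` image, or a 4D array
#'   (in the latter case `affine` must be given).
#' @param rois data frame of ROI definitions as in [motor_rois()].
#' @param tr_s sampling interval in seconds; taken from the NIfTI header
#'   when available.
#' @param affine 4 x 4 voxel-to-mm matrix, required for bare arrays.
#' @param subject_id,group_label metadata for the returned series.
#' @return A [roi_ts()] with one column per ROI.
#' @export
extract_roi_series <- function(volume4d, rois = motor_rois(), tr_s = NULL,
                               affine = NULL, subject_id = "s01",
                               group_label = NA_character_) {
  if (is.character(volume4d)) volume4d <- RNifti::readNifti(volume4d)
  if (inherits(volume4d, "niftiImage")) {
    if (is.null(affine)) affine <- RNifti::xform(volume4d)
    if (is.null(tr_s)) {
      pd <- RNifti::pixdim(volume4d)
      if (length(pd) >= 4 && pd[4] > 0) tr_s <- pd[4]
    }
  }
  if (is.null(affine)) abort("affine is required when volume4d is a bare array")
  if (is.null(tr_s)) abort("tr_s could not be determined; pass it explicitly")
  vol <- as.array(volume4d)
  if (length(dim(vol)) != 4) abort("volume4d must be 4-dimensional")
  grid_shape <- dim(vol)[1:3]
  n_vol <- dim(vol)[4]

  rois <- as_tibble(rois)
  series <- matrix(NA_real_, n_vol, nrow(rois))
  for (i in seq_len(nrow(rois))) {
    mask <- sphere_mask(rois[i, ], affine, grid_shape)
    flat <- matrix(vol, prod(grid_shape), n_vol)[as.vector(mask), , drop = FALSE]
    n_nan <- sum(!is.finite(flat))
    if (n_nan > 0) {
      abort(sprintf("ROI %s: %d non-finite voxel values inside mask",
                    rois$name[i], n_nan))
    }
    series[, i] <- colMeans(flat)
  }
  colnames(series) <- rois$name
  roi_ts(series, tr_s = tr_s, subject_id = subject_id,
         group_label = group_label)
}

# Zero-phase 4th-order Butterworth band-pass with odd-reflection padding
# (three filter lengths) applied forward and backward.
zero_phase_bandpass <- function(x, f_lo, f_hi, tr_s) {
  nyq <- 1 / (2 * tr_s)
  bf <- signal::butter(4, c(f_lo, f_hi) / nyq, type = "pass")
  nfilt <- max(length(bf$b), length(bf$a))
  pad <- min(length(x) - 1L, 3L * (nfilt - 1L))
  head_ref <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_ref <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - pad)]
  xp <- c(head_ref, x, tail_ref)
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[(pad + 1):(pad + length(x))]
}

#' Detrend and band-pass filter ROI series
#'
#' Removes each column's least-squares linear trend, then applies a
#' zero-phase (forward-backward) 4th-order Butterworth band-pass.  The
#' default band is the 0.04-0.1 Hz low-frequency window used throughout
#' the analysis.
#'
#' @param series a [roi_ts()].
#' @param f_lo,f_hi band edges in Hz; `0 < f_lo < f_hi < ` Nyquist.
#' @return The filtered [roi_ts()] (`filtered = TRUE`).
#' @export
detrend_bandpass <- function(series, f_lo = 0.04, f_hi = 0.1) {
  tr <- tr_of(series)
  nyq <- 1 / (2 * tr)
  if (!(f_lo > 0 && f_lo < f_hi)) abort("need 0 < f_lo < f_hi")
  if (f_hi >= nyq) {
    abort(sprintf("f_hi = %g Hz must be below the Nyquist frequency %g Hz for TR %g s",
                  f_hi, nyq, tr))
  }
  m <- ts_matrix(series)
  t_idx <- seq_len(nrow(m))
  detr <- apply(m, 2, function(col) stats::lm.fit(cbind(1, t_idx), col)$residuals)
  filt <- apply(detr, 2, zero_phase_bandpass, f_lo = f_lo, f_hi = f_hi,
                tr_s = tr)
  colnames(filt) <- colnames(m)
  roi_ts(filt, tr_s = tr, subject_id = attr(series, "subject_id"),
         group_label = attr(series, "group_label"), filtered = TRUE)
}

#' Motion-based subject exclusion
#'
#' Excludes a subject iff any per-volume absolute translation (relative to
#' the reference volume) strictly exceeds `trans_limit_mm` on any axis, or
#' any absolute rotation strictly exceeds `rot_limit_deg` ("more than" is
#' read strictly: boundary values are kept).
#'
#' @param motion tibble as produced by [simulate_motion()] or
#'   [read_motion()]: columns `subject_id`, `volume`, `tx`, `ty`, `tz`
#'   (mm), `rx`, `ry`, `rz` (degrees).  Rotations are taken to be in
#'   degrees already.
#' @param trans_limit_mm,rot_limit_deg exclusion limits (> 0).
#' @param n_volumes optional expected series length; a mismatch for any
#'   subject is an error.
#' @return Tibble with one row per subject: `subject_id`, `keep`,
#'   `offending_axis`, `offending_volume`, `max_translation_mm`,
#'   `max_rotation_deg`.
#' @export
motion_exclude <- function(motion, trans_limit_mm = 2.0, rot_limit_deg = 1.5,
                           n_volumes = NULL) {
  if (trans_limit_mm <= 0 || rot_limit_deg <= 0) abort("limits must be > 0")
  motion <- as_tibble(motion)
  need <- c("subject_id", "tx", "ty", "tz", "rx", "ry", "rz")
  if (!all(need %in% names(motion))) {
    abort(paste0("motion table needs columns ",
                 paste(need, collapse = ", ")))
  }
  axes <- c("tx", "ty", "tz", "rx", "ry", "rz")
  limits <- c(rep(trans_limit_mm, 3), rep(rot_limit_deg, 3))
  motion |>
    group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      if (!is.null(n_volumes) && nrow(df) != n_volumes) {
        abort(sprintf("subject %s: motion table has %d volumes, series has %d",
                      key$subject_id, nrow(df), n_volumes))
      }
      m <- abs(as.matrix(df[axes]))
      over <- sweep(m, 2, limits, FUN = ">")
      keep <- !any(over)
      if (keep) {
        off_axis <- NA_character_; off_vol <- NA_integer_
      } else {
        hit <- which(over, arr.ind = TRUE)
        first <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
        off_axis <- axes[first[2]]
        off_vol <- as.integer(df$volume[first[1]] %||% first[1])
      }
      tibble(
        keep = keep, offending_axis = off_axis, offending_volume = off_vol,
        max_translation_mm = max(m[, 1:3]), max_rotation_deg = max(m[, 4:6])
      )
    }) |>
    ungroup()
}

#' Read a six-column motion table
#'
#' Reads per-volume motion parameters stored as TSV in the column order
#' `tx ty tz rx ry rz` (translations mm, rotations degrees), with or
#' without a header.
#'
#' @param path TSV path.
#' @param subject_id subject label attached to the table.
#' @return Tibble in the [motion_exclude()] input format.
#' @export
read_motion <- function(path, subject_id = "s01") {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  dat <- readr::read_tsv(path, col_names = has_header,
                         show_col_types = FALSE)
  if (!has_header) names(dat) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  if (ncol(dat) < 6) abort("motion table must have six columns")
  tibble(subject_id = subject_id, volume = seq_len(nrow(dat)),
         tx = dat$tx, ty = dat$ty, tz = dat$tz,
         rx = dat$rx, ry = dat$ry, rz = dat$rz)
}
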