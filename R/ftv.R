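#' Construct a DCE-MRI series object
#'
#' Container for a 4D dynamic contrast-enhanced signal array with its
#' acquisition times, voxel volume and an optional region-of-interest box.
#' Axis order is (time, z, y, x); the first frame is the pre-contrast
#' acquisition. ROI bounds are 1-based inclusive index ranges.
#'
#' @param signal 4D non-negative numeric array, dims (t, z, y, x), t >= 2.
#' @param acquisition_times_s strictly increasing frame times in seconds,
#'   one per frame; the first is the pre-contrast frame.
#' @param voxel_volume_cm3 volume of one voxel in cm3 (> 0).
#' @param roi_box optional list with integer ranges `z`, `y`, `x`, each
#'   `c(lo, hi)` (1-based, inclusive); default the full array.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(signal, acquisition_times_s, voxel_volume_cm3,
                       roi_box = NULL) {
  if (!is.array(signal) || length(dim(signal)) != 4L)
    stop("'signal' must be a 4D array (time, z, y, x)")
  if (any(signal < 0, na.rm = TRUE)) stop("'signal' must be non-negative")
  nt <- dim(signal)[1]
  if (nt < 2L) stop("need at least 2 frames (pre-contrast + post-contrast)")
  if (length(acquisition_times_s) != nt)
    stop("'acquisition_times_s' must have one entry per frame")
  if (any(diff(acquisition_times_s) <= 0))
    stop("'acquisition_times_s' must be strictly increasing")
  if (!is.numeric(voxel_volume_cm3) || length(voxel_volume_cm3) != 1L ||
      voxel_volume_cm3 <= 0)
    stop("'voxel_volume_cm3' must be a single positive number")
  spatial <- dim(signal)[2:4]
  if (is.null(roi_box))
    roi_box <- list(z = c(1L, spatial[1]), y = c(1L, spatial[2]),
                    x = c(1L, spatial[3]))
  for (ax in c("z", "y", "x")) {
    b <- roi_box[[ax]]
    lim <- spatial[match(ax, c("z", "y", "x"))]
    if (is.null(b) || length(b) != 2L || any(b != round(b)) ||
        b[1] < 1 || b[2] > lim || b[1] > b[2])
      stop(sprintf("roi_box$%s must be an in-bounds 1-based range c(lo, hi)", ax))
  }
  structure(list(signal = signal,
                 acquisition_times_s = as.numeric(acquisition_times_s),
                 voxel_volume_cm3 = voxel_volume_cm3,
                 roi_box = lapply(roi_box, as.integer)),
            class = "dce_series")
}

#' Percent enhancement of post-contrast relative to pre-contrast signal
#'
#' PE = 100 * (s_post - s_pre) / s_pre, the per-voxel enhancement measure
#' thresholded in functional tumor volume computation. Voxels with zero
#' pre-contrast signal are non-evaluable and return `NA` (they are excluded
#' from FTV rather than treated as infinitely enhancing).
#'
#' @param s_pre pre-contrast signal (>= 0); vectorized.
#' @param s_post post-contrast signal (>= 0); vectorized.
#' @return Percent enhancement, with `NA` where `s_pre == 0`.
#' @export
#' @examples
#' percent_enhancement(100, 170)  # 70
percent_enhancement <- function(s_pre, s_post) {
  if (any(s_pre < 0, na.rm = TRUE) || any(s_post < 0, na.rm = TRUE))
    stop("signals must be non-negative")
  out <- 100 * (s_post - s_pre) / s_pre
  out[s_pre == 0] <- NA_real_
  out
}

#' Functional tumor volume by percent-enhancement thresholding
#'
#' Computes FTV as the summed volume of ROI voxels whose percent enhancement,
#' at the post-contrast frame acquired nearest to `eval_time_s` (about two
#' and a half minutes by default), meets or exceeds `threshold_pct`. The
#' threshold comparison is inclusive (PE >= threshold counts). Ties in frame
#' selection resolve to the earlier frame. Voxels with zero pre-contrast
#' signal are excluded and counted as non-evaluable.
#'
#' @param series a [dce_series()] object.
#' @param threshold_pct enhancement threshold in percent (default 70).
#' @param eval_time_s target post-contrast evaluation time in seconds
#'   (default 150); the nearest post-contrast frame is used.
#' @return An object of class `ftv_result`: list with `ftv_cm3`, `n_voxels`,
#'   `threshold_pct`, `eval_time_s` (the time of the frame actually used),
#'   `frame_index`, `n_roi_voxels`, `n_non_evaluable`.
#' @export
#' @examples
#' ph <- simulate_dce_phantom(c(3, 10, 10, 10), 0.01,
#'   lesion_spec = list(center = c(5, 5, 5), n_voxels = 50, pe_pct = 120),
#'   seed = 1)
#' compute_ftv(ph)$ftv_cm3
compute_ftv <- function(series, threshold_pct = 70, eval_time_s = 150) {
  stopifnot(inherits(series, "dce_series"))
  roi <- series$roi_box
  if (any(vapply(roi, function(b) b[1] > b[2], logical(1))))
    stop(sprintf("empty ROI box: z=[%d,%d] y=[%d,%d] x=[%d,%d]",
                 roi$z[1], roi$z[2], roi$y[1], roi$y[2], roi$x[1], roi$x[2]))
  times <- series$acquisition_times_s
  post_times <- times[-1]
  # nearest post-contrast frame; ties go to the earlier frame
  frame <- which.min(abs(post_times - eval_time_s)) + 1L

  zi <- roi$z[1]:roi$z[2]; yi <- roi$y[1]:roi$y[2]; xi <- roi$x[1]:roi$x[2]
  s_pre <- series$signal[1, zi, yi, xi, drop = FALSE]
  s_post <- series$signal[frame, zi, yi, xi, drop = FALSE]
  pe <- percent_enhancement(as.numeric(s_pre), as.numeric(s_post))
  n_roi <- length(pe)
  n_bad <- sum(is.na(pe))
  if (n_bad == n_roi)
    warning(sprintf("all %d ROI voxels non-evaluable (zero pre-contrast signal); FTV = 0",
                    n_roi))
  n_vox <- sum(pe >= threshold_pct, na.rm = TRUE)
  structure(list(ftv_cm3 = n_vox * series$voxel_volume_cm3,
                 n_voxels = as.integer(n_vox),
                 threshold_pct = threshold_pct,
                 eval_time_s = times[frame],
                 frame_index = frame,
                 n_roi_voxels = n_roi,
                 n_non_evaluable = as.integer(n_bad)),
            class = "ftv_result")
}

#' @export
print.ftv_result <- function(x, ...) {
  cat(sprintf("FTV %.4g cm3 (%d voxels >= %g%% PE at t = %gs; %d/%d ROI voxels non-evaluable)\n",
              x$ftv_cm3, x$n_voxels, x$threshold_pct, x$eval_time_s,
              x$n_non_evaluable, x$n_roi_voxels))
  invisible(x)
}

#' Read / write a DCE series as NIfTI
#'
#' Thin wrappers around the RNifti package for 4D DCE volumes. NIfTI stores
#' dimensions as (x, y, z, t); these wrappers transpose to and from the
#' internal (t, z, y, x) axis order. Acquisition times and voxel volume are
#' not representable in the NIfTI header here and must be supplied on read.
#'
#' @param path file path (.nii or .nii.gz).
#' @param acquisition_times_s,voxel_volume_cm3,roi_box see [dce_series()].
#' @return `read_dce_nifti` returns a [dce_series()]; `write_dce_nifti`
#'   returns `path` invisibly.
#' @export
read_dce_nifti <- function(path, acquisition_times_s, voxel_volume_cm3,
                           roi_box = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI I/O")
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stop("expected a 4D NIfTI volume")
  signal <- aperm(arr, c(4, 3, 2, 1))  # (x,y,z,t) -> (t,z,y,x)
  dce_series(signal, acquisition_times_s, voxel_volume_cm3, roi_box)
}

#' @rdname read_dce_nifti
#' @param series a [dce_series()] object.
#' @export
write_dce_nifti <- function(series, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI I/O")
  stopifnot(inherits(series, "dce_series"))
  arr <- aperm(series$signal, c(4, 3, 2, 1))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}
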