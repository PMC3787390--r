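#' ROI-integrated intensity timecourse
#'
#' @param times numeric vector, minutes, strictly increasing.
#' @param intensities nonnegative intensities, same length.
#' @param roi_id identifier for the region of interest.
#' @return object of class `time_series`.
#' @export
time_series <- function(times, intensities, roi_id = "roi") {
  if (length(times) != length(intensities))
    stop("`times` and `intensities` must have equal length", call. = FALSE)
  if (length(times) < 1) stop("empty time series", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(intensities)))
    stop("times and intensities must be finite", call. = FALSE)
  structure(list(times = times, intensities = intensities, roi_id = roi_id),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> '%s': %d frames, t = [%g, %g] min, I = [%g, %g]\n",
              x$roi_id, length(x$times), min(x$times), max(x$times),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

# intensity at time t (minutes), linearly interpolated between frames
ts_intensity <- function(ts, t) {
  if (t < min(ts$times) || t > max(ts$times))
    stop(sprintf("time %g min outside the series range [%g, %g]",
                 t, min(ts$times), max(ts$times)), call. = FALSE)
  stats::approx(ts$times, ts$intensities, xout = t)$y
}

#' Extract an ROI timecourse from an image stack
#'
#' Mean intensity within a region of interest, frame by frame.
#'
#' @param stack list of [image2d()] frames sharing one shape.
#' @param times frame timestamps in minutes (strictly increasing, one per
#'   frame).
#' @param roi either a logical mask matrix matching the frames, or an integer
#'   vector `c(row1, row2, col1, col2)` describing a pixel rectangle.
#' @param roi_id identifier carried into the result.
#' @return a [time_series()].
#' @export
roi_timecourse <- function(stack, times, roi, roi_id = "roi") {
  if (length(stack) < 1) stop("empty stack", call. = FALSE)
  if (length(times) != length(stack))
    stop("one timestamp per frame required", call. = FALSE)
  d <- dim(stack[[1]]$values)
  if (is.logical(roi)) {
    if (!all(dim(roi) == d)) stop("roi mask must match frame shape", call. = FALSE)
    if (!any(roi)) stop("empty roi", call. = FALSE)
    sel <- roi
  } else {
    if (length(roi) != 4) stop("rectangle roi must be c(row1, row2, col1, col2)",
                               call. = FALSE)
    if (roi[1] < 1 || roi[3] < 1 || roi[2] > d[1] || roi[4] > d[2] ||
        roi[1] > roi[2] || roi[3] > roi[4])
      stop("roi rectangle out of image bounds", call. = FALSE)
    sel <- matrix(FALSE, d[1], d[2])
    sel[roi[1]:roi[2], roi[3]:roi[4]] <- TRUE
  }
  vals <- vapply(stack, function(f) {
    if (!all(dim(f$values) == d)) stop("frames differ in shape", call. = FALSE)
    mean(f$values[sel])
  }, numeric(1))
  time_series(times, vals, roi_id)
}

#' Fold increase of ROI intensity between two times
#'
#' `I(t) / I(t0)` with linear interpolation between frames. The raw ratio; no
#' background subtraction unless a `background` level is supplied, in which
#' case it is subtracted from both intensities first.
#'
#' @param ts a [time_series()].
#' @param t0 baseline time (minutes).
#' @param t comparison time (minutes), `> t0`.
#' @param background optional constant background to subtract (default 0).
#' @return unitless fold change.
#' @examples
#' ts <- time_series(c(0, 30), c(10, 102))
#' fold_increase(ts, 0, 30)  # 10.2
#' @export
fold_increase <- function(ts, t0, t, background = 0) {
  stopifnot(inherits(ts, "time_series"))
  if (t0 >= t) stop("`t0` must be earlier than `t`", call. = FALSE)
  i0 <- ts_intensity(ts, t0) - background
  it <- ts_intensity(ts, t) - background
  if (i0 <= 0) stop("baseline intensity must be positive", call. = FALSE)
  it / i0
}

#' FRAP recovery percentage
#'
#' Percent recovery of photobleached fluorescence:
#' `100 * (I(t) - I(bleach)) / (I(pre) - I(bleach))`, 0 at the bleach,
#' 100 at full recovery to the pre-bleach level.
#'
#' @param ts a [time_series()].
#' @param t_pre pre-bleach reference time (minutes).
#' @param t_bleach time of the post-bleach measurement (minutes),
#'   `> t_pre`.
#' @param t recovery time (minutes), `> t_bleach`.
#' @return percent.
#' @export
recovery_percent <- function(ts, t_pre, t_bleach, t) {
  stopifnot(inherits(ts, "time_series"))
  if (!(t_pre < t_bleach && t_bleach < t))
    stop("need t_pre < t_bleach < t", call. = FALSE)
  ipre <- ts_intensity(ts, t_pre)
  ibl <- ts_intensity(ts, t_bleach)
  it <- ts_intensity(ts, t)
  if (ipre <= ibl)
    stop("degenerate bleach: pre-bleach intensity must exceed post-bleach",
         call. = FALSE)
  100 * (it - ibl) / (ipre - ibl)
}

#' Extrapolate total dots per cell from per-frame counts
#'
#' Naive volumetric and temporal extrapolation of the number of transport
#' intermediates observed per imaging frame: dots per frame, times frames over
#' the observation period, times the number of focal slabs needed to cover the
#' cell thickness. Reported both unrounded and to one significant figure (the
#' order-of-magnitude presentation).
#'
#' @param dots_per_frame mean dots counted per frame (>= 0; default 6).
#' @param frame_interval_s seconds per frame (> 0; default 5).
#' @param duration_min observation period in minutes (> 0; default 30).
#' @param focal_depth_nm focal-plane thickness in nm (> 0; default 500).
#' @param cell_thickness_um cell thickness in micrometres (> 0; default 5).
#' @return list with `unrounded`, `rounded` (one significant figure),
#'   `n_frames` and `n_slabs`.
#' @examples
#' estimate_total_dots()  # 6 * 360 * 10 = 21600, ~20000
#' @export
estimate_total_dots <- function(dots_per_frame = 6, frame_interval_s = 5,
                                duration_min = 30, focal_depth_nm = 500,
                                cell_thickness_um = 5) {
  stopifnot_scalar_num(dots_per_frame, "dots_per_frame", 0)
  stopifnot_scalar_num(frame_interval_s, "frame_interval_s", 0, strict = TRUE)
  stopifnot_scalar_num(duration_min, "duration_min", 0, strict = TRUE)
  stopifnot_scalar_num(focal_depth_nm, "focal_depth_nm", 0, strict = TRUE)
  stopifnot_scalar_num(cell_thickness_um, "cell_thickness_um", 0, strict = TRUE)
  n_frames <- duration_min * 60 / frame_interval_s
  n_slabs <- cell_thickness_um * 1000 / focal_depth_nm
  unrounded <- dots_per_frame * n_frames * n_slabs
  list(unrounded = unrounded, rounded = signif(unrounded, 1),
       n_frames = n_frames, n_slabs = n_slabs)
}
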