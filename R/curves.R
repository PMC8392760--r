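#' Frame schedule for a dynamic PET acquisition
#'
#' A frame schedule records the start time and duration (both in seconds) of
#' each reconstructed time-frame. Frames must be contiguous and start at
#' injection (t = 0).
#'
#' @param duration Numeric vector of frame durations in seconds, all > 0.
#' @return An object of class `frame_schedule` with elements `start`,
#'   `duration` (seconds per frame).
#' @seealso [default_frame_schedule()]
#' @export
frame_schedule <- function(duration) {
  duration <- as.numeric(duration)
  if (length(duration) == 0L || any(!is.finite(duration)) || any(duration <= 0))
    stop("frame durations must be finite and > 0")
  structure(
    list(start = cumsum(c(0, duration[-length(duration)])),
         duration = duration),
    class = "frame_schedule")
}

#' Default 26-frame, 10-minute schedule
#'
#' The standard framing for a 10 min dynamic 15O-water brain scan:
#' 1x10, 8x5, 4x10, 2x15, 3x20, 2x30 and 6x60 s (26 frames, 600 s total).
#'
#' @return A [frame_schedule()].
#' @export
#' @examples
#' s <- default_frame_schedule()
#' n_frames(s)          # 26
#' total_duration(s)    # 600
default_frame_schedule <- function() {
  frame_schedule(c(10, rep(5, 8), rep(10, 4), rep(15, 2),
                   rep(20, 3), rep(30, 2), rep(60, 6)))
}

#' @rdname frame_schedule
#' @param schedule A `frame_schedule`.
#' @export
n_frames <- function(schedule) length(schedule$duration)

#' @rdname frame_schedule
#' @export
total_duration <- function(schedule) sum(schedule$duration)

#' @rdname frame_schedule
#' @export
frame_midpoints <- function(schedule) schedule$start + schedule$duration / 2

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("frame_schedule: %d frames, %.0f s total (%.0f-%.0f s durations)\n",
              n_frames(x), total_duration(x), min(x$duration), max(x$duration)))
  invisible(x)
}

#' Time-activity curve
#'
#' The universal currency between pipeline stages: activity concentration
#' (kBq/mL) sampled over time (seconds). A curve is either frame-based
#' (samples at frame midpoints) or on a uniform grid (typically 1 Hz).
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param value Activity concentration in kBq/mL; finite.
#' @param grid_kind `"frame"` or `"uniform"`.
#' @return An object of class `tac` (a data-frame-like list with `t`,
#'   `value` and a `grid_kind` attribute).
#' @export
new_tac <- function(t, value, grid_kind = c("frame", "uniform")) {
  grid_kind <- match.arg(grid_kind)
  t <- as.numeric(t); value <- as.numeric(value)
  if (length(t) != length(value)) stop("t and value must have equal length")
  if (any(!is.finite(t)) || any(!is.finite(value)))
    stop("tac samples must be finite")
  if (length(t) > 1 && any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (grid_kind == "uniform" && length(t) > 2) {
    dt <- diff(t)
    if (max(abs(dt - dt[1])) > 1e-9) stop("uniform tac must be evenly spaced")
  }
  structure(list(t = t, value = value), grid_kind = grid_kind, class = "tac")
}

#' @rdname new_tac
#' @param x A `tac`.
#' @export
tac_dt <- function(x) {
  if (attr(x, "grid_kind") != "uniform") stop("tac is not on a uniform grid")
  if (length(x$t) < 2) stop("need >= 2 samples to define a grid step")
  x$t[2] - x$t[1]
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("tac (%s grid): %d samples, t = [%g, %g] s, peak %.3g kBq/mL\n",
              attr(x, "grid_kind"), length(x$t), min(x$t), max(x$t),
              max(x$value)))
  invisible(x)
}

#' Resample a frame-based curve to a uniform 1-second grid
#'
#' Frame values are taken to sit at frame midpoints; samples are linearly
#' interpolated between midpoints. Before the first midpoint the curve is
#' linearly extrapolated from 0 at t = 0 (bolus scans start at injection, so
#' there is no pre-injection activity); after the last midpoint the last value
#' is held. The output covers t = 0 .. total scan duration at 1-s steps.
#'
#' @param tac A frame-based [new_tac()].
#' @param schedule The matching [frame_schedule()].
#' @return A uniform-grid `tac`.
#' @export
resample_to_1s <- function(tac, schedule) {
  if (attr(tac, "grid_kind") != "frame")
    stop("resample_to_1s expects a frame-based tac")
  if (length(tac$value) != n_frames(schedule))
    stop("tac length does not match the frame schedule")
  mid <- frame_midpoints(schedule)
  tt <- seq(0, floor(total_duration(schedule)), by = 1)
  xs <- c(0, mid)
  ys <- c(0, tac$value)
  v <- stats::approx(xs, ys, xout = tt, rule = 2)$y
  new_tac(tt, v, grid_kind = "uniform")
}

#' Restrict a uniform curve to the analysis window
#'
#' Only data from the first part of the scan are used for kinetic analysis,
#' to minimise noise from late frames. The window is the closed interval
#' t in \[0, end\] seconds; the default 360 s (6 min) yields 361 samples on a
#' 1-s grid. Idempotent.
#'
#' @param tac A uniform-grid `tac` covering at least `end` seconds.
#' @param end Window end in seconds (inclusive); default 360.
#' @return The windowed `tac`.
#' @export
tac_window <- function(tac, end = 360) {
  if (attr(tac, "grid_kind") != "uniform")
    stop("tac_window expects a uniform-grid tac")
  if (max(tac$t) < end) stop("curve shorter than the requested window")
  keep <- tac$t <= end + 1e-9
  new_tac(tac$t[keep], tac$value[keep], grid_kind = "uniform")
}

#' Average a uniform 1-s curve back onto a frame schedule
#'
#' Each frame value is the mean of the 1-s samples falling in
#' \[start, start + duration). Frames extending past the end of the curve are
#' dropped. Used for point-by-point curve comparison on the original PET
#' framing.
#'
#' @param tac A uniform 1-s `tac`.
#' @param schedule A [frame_schedule()].
#' @return A frame-based `tac` (t at frame midpoints of retained frames).
#' @export
rebin_to_schedule <- function(tac, schedule) {
  if (attr(tac, "grid_kind") != "uniform")
    stop("rebin_to_schedule expects a uniform-grid tac")
  tmax <- max(tac$t)
  keep <- which(schedule$start + schedule$duration <= tmax + 1e-9)
  if (length(keep) == 0L) stop("no complete frames within the curve support")
  v <- vapply(keep, function(i) {
    s <- schedule$start[i]; d <- schedule$duration[i]
    mean(tac$value[tac$t >= s - 1e-9 & tac$t < s + d - 1e-9])
  }, numeric(1))
  new_tac(frame_midpoints(schedule)[keep], v, grid_kind = "frame")
}
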