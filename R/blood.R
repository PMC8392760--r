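#' Mono-exponential dispersion kernel
#'
#' Blood drawn through vessels and detector tubing smears the bolus; the
#' measured signal is the true arterial curve convolved with
#' d(t) = (1/tau) exp(-t/tau). On a discrete grid the kernel weight of bin k
#' is the integral of d over \[k dt, (k+1) dt\), which is exact for
#' piecewise-constant signals; weights are renormalised to unit sum so the
#' curve area is preserved despite tail truncation.
#'
#' @param tau Dispersion time constant in seconds, >= 0.
#' @param dt Grid step in seconds.
#' @param n Number of kernel bins (curve length).
#' @return Numeric vector of kernel weights summing to 1 (or a unit spike for
#'   tau = 0).
#' @keywords internal
dispersion_kernel <- function(tau, dt, n) {
  if (tau < 0) stop("tau must be >= 0")
  if (tau == 0) return(c(1, rep(0, n - 1L)))
  k <- 0:(n - 1L)
  w <- exp(-k * dt / tau) * (1 - exp(-dt / tau))
  w / sum(w)
}

#' Apply dispersion to an arterial curve (forward model)
#'
#' Convolves the curve with the mono-exponential dispersion kernel, modelling
#' the smearing a wrist-sampled blood signal undergoes relative to the true
#' arterial input function. Output length equals input length; the curve
#' integral is preserved up to kernel-tail truncation.
#'
#' @param tac A uniform-grid [new_tac()].
#' @param tau Dispersion constant in seconds (15 s is the standard value for
#'   this sampling geometry).
#' @return The dispersed `tac`.
#' @export
apply_dispersion <- function(tac, tau) {
  if (tau < 0) stop("tau must be >= 0")
  dt <- tac_dt(tac)
  n <- length(tac$value)
  w <- dispersion_kernel(tau, dt, n)
  out <- stats::convolve(tac$value, rev(w), type = "open")[seq_len(n)]
  new_tac(tac$t, out, grid_kind = "uniform")
}

#' Correct a measured blood curve for dispersion
#'
#' Inverts the mono-exponential dispersion model analytically:
#' C_A(t) = g(t) + tau * dg/dt. The derivative uses central differences with
#' one-sided differences at the ends; an optional moving-average pre-smoothing
#' of width `smooth_width` samples can be applied for noisy detector data.
#'
#' @param g A uniform-grid measured blood `tac` (>= 3 samples).
#' @param tau Dispersion constant in seconds.
#' @param smooth_width Odd moving-average width in samples; 0 (default)
#'   disables smoothing.
#' @return The dispersion-corrected `tac`.
#' @export
correct_dispersion <- function(g, tau, smooth_width = 0) {
  if (tau < 0) stop("tau must be >= 0")
  v <- g$value
  n <- length(v)
  if (n < 3) stop("need >= 3 samples to differentiate")
  if (smooth_width > 1) {
    k <- rep(1 / smooth_width, smooth_width)
    sm <- stats::filter(v, k, sides = 2)
    v <- ifelse(is.na(sm), v, as.numeric(sm))
  }
  dt <- tac_dt(g)
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  new_tac(g$t, v + tau * d, grid_kind = "uniform")
}

#' Continuous blood measurement with a single calibration sample
#'
#' @param counts A uniform 1-s `tac` of detector counts (arbitrary units).
#' @param cal_time Time of the calibration blood sample in seconds.
#' @param cal_value Well-counter concentration of that sample, kBq/mL (> 0).
#' @return An object of class `blood_measurement`.
#' @export
blood_measurement <- function(counts, cal_time, cal_value) {
  if (attr(counts, "grid_kind") != "uniform")
    stop("counts must be on a uniform grid")
  if (cal_time < min(counts$t) || cal_time > max(counts$t))
    stop("calibration time outside the measured interval")
  if (!is.finite(cal_value) || cal_value <= 0)
    stop("calibration value must be > 0")
  structure(list(counts = counts, cal_time = cal_time, cal_value = cal_value),
            class = "blood_measurement")
}

#' Calibrate continuous blood counts to absolute concentration
#'
#' Scales the whole detector curve so that its mean over a +/- `half_window`
#' second window around the calibration draw equals the well-counter value of
#' that sample. The window suppresses 1-Hz detector noise; the factor is
#' invariant to any rescaling of the raw counts.
#'
#' @param meas A [blood_measurement()].
#' @param half_window Half-width of the averaging window in seconds.
#' @return A calibrated uniform `tac` in kBq/mL.
#' @export
calibrate_blood <- function(meas, half_window = 10) {
  sel <- abs(meas$counts$t - meas$cal_time) <= half_window + 1e-9
  denom <- mean(meas$counts$value[sel])
  if (!is.finite(denom) || denom <= 0)
    stop("non-positive curve mean in the calibration window")
  f <- meas$cal_value / denom
  new_tac(meas$counts$t, meas$counts$value * f, grid_kind = "uniform")
}

shift_curve <- function(v, s) {
  n <- length(v)
  if (s == 0) return(v)
  if (s > 0) c(rep(0, s), v[seq_len(n - s)]) else c(v[(-s + 1):n], rep(0, -s))
}

#' Align an arterial curve to the carotid IDIF by delay shifting
#'
#' Wrist sampling sees the bolus later than the brain does. The corrected
#' arterial curve is shifted by the integer-second lag (within
#' +/- `max_shift`) that maximises its dot product with the 10-voxel carotid
#' IDIF; ties are broken toward the smallest absolute shift. The shifted
#' curve is zero-padded outside its support.
#'
#' @param aif Uniform 1-s arterial `tac`.
#' @param idif10 Uniform 1-s carotid IDIF `tac` on the same grid.
#' @param max_shift Maximum shift magnitude in seconds (default 30).
#' @return List with `aif` (shifted `tac`) and `shift` (seconds; positive
#'   means the input was moved later in time).
#' @export
align_delay <- function(aif, idif10, max_shift = 30) {
  if (length(aif$t) != length(idif10$t))
    stop("curves must share a grid of equal length")
  if (max_shift < 0) stop("max_shift must be >= 0")
  if (all(aif$value == 0) || all(idif10$value == 0))
    stop("degenerate all-zero curve: delay is undefined")
  shifts <- seq.int(-max_shift, max_shift)
  shifts <- shifts[order(abs(shifts), shifts)]  # tie-break: smallest |s| first
  score <- vapply(shifts, function(s)
    sum(shift_curve(aif$value, s) * idif10$value), numeric(1))
  best <- shifts[which.max(score)]
  list(aif = new_tac(aif$t, shift_curve(aif$value, best), grid_kind = "uniform"),
       shift = best)
}

#' Recover the brain-local arterial input function from a wrist measurement
#'
#' The full blood pipeline: dispersion correction (analytic inversion with
#' fixed tau), calibration against the single well-counter sample, windowing
#' to the analysis interval, and delay alignment to the carotid IDIF10 curve.
#'
#' @param meas A [blood_measurement()].
#' @param idif10 The carotid IDIF10 `tac` (uniform 1-s, windowed).
#' @param tau Dispersion constant, seconds.
#' @param max_shift Delay search half-range, seconds.
#' @param window_end Analysis window end, seconds.
#' @return List with `aif` (windowed, aligned `tac`), `shift` (s) and the
#'   applied calibration-corrected curve before alignment (`aif_unshifted`).
#' @export
recover_aif <- function(meas, idif10, tau = 15, max_shift = 30,
                        window_end = 360) {
  corr <- correct_dispersion(meas$counts, tau)
  cal <- calibrate_blood(blood_measurement(corr, meas$cal_time, meas$cal_value))
  win <- tac_window(cal, window_end)
  al <- align_delay(win, idif10, max_shift)
  list(aif = al$aif, shift = al$shift, aif_unshifted = win)
}
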