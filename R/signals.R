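# Raw signal -> tilt angles + SMA (the feature pipeline feeding the
# classifier).

#' Three-point median filter
#'
#' Smooths each axis with a running median of three samples. Endpoints are
#' handled by edge replication, which for a width-3 window is equivalent to
#' leaving the first and last sample unchanged (the median of
#' \{x1, x1, x2\} is x1), so the output length equals the input length.
#'
#' @param signal An [accel_signal].
#' @return An [accel_signal] of the same length.
#' @export
median_filter3 <- function(signal) {
  stopifnot(inherits(signal, "accel_signal"))
  if (n_samples(signal) < 3L)
    stop("median_filter3 needs at least 3 samples")
  out <- signal
  out$xyz <- apply(signal$xyz, 2, function(x)
    stats::runmed(x, k = 3, endrule = "keep"))
  out
}

# Second-order Butterworth low-pass applied forward-backward with
# odd-reflection padding at both ends. signal::filtfilt pads with nothing and
# leaves large end transients at cutoffs far below Nyquist, so the padded
# pass is done here. Pad length covers ~6 filter time constants, so the
# zero-initial-state startup transient decays below ~1e-10.
zero_phase_lowpass <- function(x, rate, cutoff_hz, order = 2) {
  flt <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  n <- length(x)
  np <- min(n - 1L, as.integer(ceiling(6 * rate / cutoff_hz)))
  pre <- 2 * x[1] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  xp <- c(pre, x, post)
  y <- rev(signal::filter(flt, rev(signal::filter(flt, xp))))
  as.numeric(y[(np + 1L):(np + n)])
}

#' Extract the gravitational component of an acceleration signal
#'
#' Separates sensor tilt from body movement by low-pass filtering each axis.
#' A Butterworth IIR low-pass (default second order, 0.25 Hz cutoff) is
#' applied forward-backward so the gravity estimate has zero phase lag with
#' respect to the raw signal; edges are odd-reflection padded. The DC gain is
#' exactly 1, so a constant input passes through unchanged.
#'
#' @param signal An [accel_signal] (normally median-filtered first).
#' @param cutoff_hz Low-pass cutoff in Hz; must be below the Nyquist
#'   frequency. Default 0.25.
#' @param order Filter order, default 2.
#' @return A `gravity_series` with the same shape as the input.
#' @export
extract_gravity <- function(signal, cutoff_hz = 0.25, order = 2) {
  stopifnot(inherits(signal, "accel_signal"))
  if (cutoff_hz <= 0 || cutoff_hz >= signal$rate / 2)
    stop("`cutoff_hz` must lie in (0, rate/2)")
  xyz <- apply(signal$xyz, 2, zero_phase_lowpass,
               rate = signal$rate, cutoff_hz = cutoff_hz, order = order)
  mag <- sqrt(rowSums(xyz^2))
  if (any(mag < 0.5 | mag > 1.5))
    warning(sprintf(
      "gravity magnitude outside [0.5, 1.5] g for %.1f%% of samples: check sensor wear",
      100 * mean(mag < 0.5 | mag > 1.5)))
  new_gravity_series(signal, xyz)
}

#' Compute tilt angles from a gravity series
#'
#' Per-sample orientation of the sensor relative to the measured gravity
#' reaction:
#' \itemize{
#'   \item `phi` = atan2(sqrt(gy^2 + gz^2), gx), in \[0, 180\] degrees —
#'     inclination of the longitudinal (x) axis to gravity; 90 when lying,
#'     0 when upright.
#'   \item `theta` = atan2(gy, gz), in (-180, 180\] degrees — roll about the
#'     longitudinal axis; 0 supine, ±90 side-lying, ±180 prone. Positive
#'     theta is rotation toward the participant's right side.
#'   \item `psi` = atan2(gy, sqrt(gx^2 + gz^2)), in \[-90, 90\] degrees —
#'     second horizontal tilt.
#' }
#' Samples with (near-)zero gravity magnitude are flagged and carry the
#' previous sample's angles forward.
#'
#' @param gravity A `gravity_series` from [extract_gravity()].
#' @return An uncorrected `orientation_series`.
#' @export
compute_tilt_angles <- function(gravity) {
  stopifnot(inherits(gravity, "gravity_series"))
  gx <- gravity$xyz[, 1]; gy <- gravity$xyz[, 2]; gz <- gravity$xyz[, 3]
  mag <- sqrt(gx^2 + gy^2 + gz^2)
  flagged <- mag < 1e-12 | !is.finite(mag)
  if (all(flagged)) stop("gravity magnitude is zero everywhere")
  deg <- 180 / pi
  phi <- atan2(sqrt(gy^2 + gz^2), gx) * deg
  theta <- atan2(gy, gz) * deg
  psi <- atan2(gy, sqrt(gx^2 + gz^2)) * deg
  if (any(flagged)) {
    ok <- which(!flagged)
    # carry last valid angles forward (and the first valid one backward)
    idx <- findInterval(seq_along(mag), ok)
    idx[idx == 0L] <- 1L
    src <- ok[idx]
    phi <- phi[src]; theta <- theta[src]; psi <- psi[src]
  }
  new_orientation_series(theta, psi, phi, gravity$rate, gravity$start_offset,
                         corrected = FALSE, flagged = flagged)
}

#' Baseline-correct tilt angles against a supine rest window
#'
#' Accounts for sensor mounting offsets and drift by subtracting the mean
#' angles observed during a supine rest interval, so that after correction
#' the horizontal tilt angles (theta, psi) are zero and the vertical tilt
#' angle (phi) is 90 degrees in supine rest. The caller is responsible for
#' choosing a window whose SMA is below the rest-activity threshold.
#'
#' @param angles An `orientation_series`.
#' @param window Numeric `c(start_s, end_s)` on the session clock; duration
#'   must be at least 2 s and the window must lie within the series.
#' @return A list with `offsets` (class `calibration_offsets`: `d_theta`,
#'   `d_psi`, `d_phi`, `window`) and `angles` (the corrected series, theta
#'   re-wrapped to (-180, 180\]).
#' @export
calibrate_supine <- function(angles, window) {
  stopifnot(inherits(angles, "orientation_series"))
  if (length(window) != 2L || diff(window) < 2)
    stop("calibration window must span at least 2 s")
  t <- angles$start_offset + (seq_along(angles$theta) - 1L) / angles$rate
  series_end <- angles$start_offset + length(angles$theta) / angles$rate
  if (window[1] < t[1] - 1e-9 || window[2] > series_end + 1e-9)
    stop("calibration window lies outside the angle series")
  in_win <- t >= window[1] & t <= window[2]
  offsets <- structure(
    list(d_theta = mean(angles$theta[in_win]),
         d_psi = mean(angles$psi[in_win]),
         d_phi = mean(angles$phi[in_win]) - 90,
         window = window),
    class = "calibration_offsets"
  )
  corrected <- angles
  corrected$theta <- wrap_angle(angles$theta - offsets$d_theta)
  corrected$psi <- angles$psi - offsets$d_psi
  corrected$phi <- angles$phi - offsets$d_phi
  corrected$corrected <- TRUE
  list(offsets = offsets, angles = corrected)
}

#' @export
print.calibration_offsets <- function(x, ...) {
  cat(sprintf(
    "<calibration_offsets> d_theta %.2f, d_psi %.2f, d_phi %.2f deg (window %.1f-%.1f s)\n",
    x$d_theta, x$d_psi, x$d_phi, x$window[1], x$window[2]))
  invisible(x)
}

# cumulative trapezoid of y on a uniform grid with spacing dt; ct[1] = 0
cumtrapz_uniform <- function(y, dt) {
  c(0, cumsum((dt / 2) * (y[-1] + y[-length(y)])))
}

#' Signal magnitude area (SMA)
#'
#' Quantifies bodily movement: the body acceleration (raw minus gravity) is
#' rectified per axis, integrated over a sliding window (trapezoidal rule),
#' summed across the three axes, and normalised by the window length. With
#' the default 1 s window the SMA value is the mean rectified body
#' acceleration in g summed over axes; the default 0.2 s hop emits SMA
#' natively at the 5 Hz epoch rate. Window k covers
#' `[k * step_s, k * step_s + window_s]` relative to the signal start; the
#' reported time of each value is the window centre.
#'
#' @param raw The (median-filtered) [accel_signal].
#' @param gravity The matching `gravity_series`.
#' @param window_s Window length in seconds, default 1.
#' @param step_s Hop between windows in seconds, default 0.2.
#' @return An `sma_series` with `values` (g), `times` (window centres, session
#'   clock), `window_s`, `step_s`.
#' @export
compute_sma <- function(raw, gravity, window_s = 1, step_s = 0.2) {
  stopifnot(inherits(raw, "accel_signal"), inherits(gravity, "gravity_series"))
  if (n_samples(raw) != nrow(gravity$xyz))
    stop("raw and gravity series must have equal length")
  rate <- raw$rate
  wlen <- round(window_s * rate)
  if (wlen < 2) stop("window_s * rate must be at least 2")
  hop <- step_s * rate
  if (abs(hop - round(hop)) > 1e-9)
    stop("step_s must be an integer number of samples")
  hop <- as.integer(round(hop))
  b <- abs(raw$xyz - gravity$xyz)
  ct <- cumtrapz_uniform(rowSums(b), 1 / rate)
  n <- n_samples(raw)
  starts <- seq.int(1L, n - wlen, by = hop)
  values <- (ct[starts + wlen] - ct[starts]) / window_s
  times <- raw$start_offset + (starts - 1L) / rate + window_s / 2
  new_sma_series(values, times, window_s, step_s)
}

#' Fuse chest and thigh features into a 5 Hz epoch frame
#'
#' Builds the classifier's input: one record per 0.2 s epoch over the
#' temporal overlap of the two sensors, carrying the baseline-corrected
#' angles of both sensors sampled at the epoch centre, the SMA of the window
#' centred on the epoch, and two quality channels: the gravity magnitude at
#' the epoch centre (`gmag_*`, used by the classifier's wear guard) and the
#' thigh inclination computed from the raw signal (`phi_t_inst`, used by the
#' cycling detector, since pedalling frequencies are removed from the
#' gravity-derived angles by the 0.25 Hz low-pass).
#'
#' @param chest,thigh Lists with elements `angles` (`orientation_series`),
#'   `sma` (`sma_series`), and optionally `gravity` (`gravity_series`) and
#'   `raw` ([accel_signal]). Without `gravity` the magnitude guard channel is
#'   set to 1; without `raw`, `phi_t_inst` falls back to the gravity-derived
#'   thigh phi.
#' @param epoch_s Epoch length in seconds (default 0.2, i.e. 5 Hz).
#' @return A `data.frame` of class `epoch_frame` with columns `epoch_s`
#'   (epoch start, session clock), `phi_mc`, `theta_mc`, `psi_mc`, `phi_t`,
#'   `theta_t`, `psi_t`, `sma_mc`, `sma_t`, `phi_t_inst`, `gmag_mc`,
#'   `gmag_t`.
#' @export
build_epoch_frame <- function(chest, thigh, epoch_s = 0.2) {
  for (side in list(chest, thigh)) {
    stopifnot(inherits(side$angles, "orientation_series"),
              inherits(side$sma, "sma_series"))
  }
  # each sample covers 1/rate of time, so n samples span n/rate seconds
  span <- function(a) {
    t0 <- a$start_offset
    c(t0, t0 + length(a$theta) / a$rate)
  }
  sc <- span(chest$angles); st <- span(thigh$angles)
  t0 <- max(sc[1], st[1]); t1 <- min(sc[2], st[2])
  if (t1 - t0 < epoch_s) stop("chest and thigh streams do not overlap")
  n_ep <- floor((t1 - t0) / epoch_s + 1e-9)
  starts <- t0 + (seq_len(n_ep) - 1L) * epoch_s
  centers <- starts + epoch_s / 2

  at_center <- function(vec, rate, off) {
    idx <- round((centers - off) * rate) + 1L
    vec[pmin(pmax(idx, 1L), length(vec))]
  }
  sma_at <- function(sma) {
    idx <- vapply(centers, function(tc) which.min(abs(sma$times - tc)), 1L)
    sma$values[idx]
  }
  gmag_at <- function(side) {
    if (is.null(side$gravity)) return(rep(1, n_ep))
    mag <- sqrt(rowSums(side$gravity$xyz^2))
    at_center(mag, side$gravity$rate, side$gravity$start_offset)
  }
  ang <- function(a, which) at_center(a[[which]], a$rate, a$start_offset)

  phi_t_inst <- if (is.null(thigh$raw)) {
    ang(thigh$angles, "phi")
  } else {
    r <- thigh$raw
    gx <- r$xyz[, 1]; gy <- r$xyz[, 2]; gz <- r$xyz[, 3]
    phi_raw <- atan2(sqrt(gy^2 + gz^2), gx) * 180 / pi
    at_center(phi_raw, r$rate, r$start_offset)
  }

  frame <- data.frame(
    epoch_s = starts,
    phi_mc = ang(chest$angles, "phi"),
    theta_mc = ang(chest$angles, "theta"),
    psi_mc = ang(chest$angles, "psi"),
    phi_t = ang(thigh$angles, "phi"),
    theta_t = ang(thigh$angles, "theta"),
    psi_t = ang(thigh$angles, "psi"),
    sma_mc = sma_at(chest$sma),
    sma_t = sma_at(thigh$sma),
    phi_t_inst = phi_t_inst,
    gmag_mc = gmag_at(chest),
    gmag_t = gmag_at(thigh)
  )
  class(frame) <- c("epoch_frame", "data.frame")
  attr(frame, "rate") <- 1 / epoch_s
  frame
}
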