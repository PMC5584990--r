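#' Uniformly sampled angular eye position trace
#'
#' An `eye_trace` holds horizontal eye angle (degrees) sampled at a fixed
#' rate. Positive angles follow the configured nasal/temporal convention of
#' the recording; the synthetic generator uses rightward-positive.
#'
#' @param time_s Numeric vector of sample times in seconds, uniformly spaced.
#' @param position_deg Numeric vector of eye angles in degrees, same length
#'   as `time_s`.
#' @param sample_rate_hz Sampling rate in Hz. Inferred from `time_s` when
#'   missing.
#' @return An object of class `eye_trace`: a list with fields `time_s`,
#'   `position_deg`, `sample_rate_hz`.
#' @examples
#' tr <- eye_trace(seq(0, 1, by = 0.01), sin(seq(0, 1, by = 0.01) * 2 * pi))
#' tr$sample_rate_hz
#' @export
eye_trace <- function(time_s, position_deg, sample_rate_hz = NULL) {
  time_s <- as.numeric(time_s)
  position_deg <- as.numeric(position_deg)
  if (length(time_s) != length(position_deg)) {
    stop("`time_s` and `position_deg` must have equal length", call. = FALSE)
  }
  if (length(time_s) < 2L) stop("trace needs at least 2 samples", call. = FALSE)
  .check_uniform(time_s)
  if (!all(is.finite(position_deg))) {
    stop("`position_deg` must be finite", call. = FALSE)
  }
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- 1 / stats::median(diff(time_s))
  }
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be positive", call. = FALSE)
  }
  structure(
    list(time_s = time_s, position_deg = position_deg,
         sample_rate_hz = sample_rate_hz),
    class = "eye_trace"
  )
}

#' Two-channel AMR sensor voltage trace
#'
#' Holds the two differential voltages `m1(t)`, `m2(t)` recorded from the
#' angular magnetic field sensor, plus optional TTL sync-pulse onset times
#' used for alignment with video streams.
#'
#' @param time_s Uniform sample times (s).
#' @param v_mV Numeric matrix with one row per sample and exactly two
#'   columns (channel 1, channel 2), in millivolts.
#' @param sample_rate_hz Sampling rate (Hz); inferred when missing.
#' @param ttl_pulse_times_s Optional numeric vector of sync pulse onset
#'   times, each within the span of `time_s`.
#' @return An object of class `sensor_trace`.
#' @export
sensor_trace <- function(time_s, v_mV, sample_rate_hz = NULL,
                         ttl_pulse_times_s = NULL) {
  time_s <- as.numeric(time_s)
  v_mV <- as.matrix(v_mV)
  if (ncol(v_mV) != 2L) stop("`v_mV` must have exactly 2 channels", call. = FALSE)
  if (nrow(v_mV) != length(time_s)) {
    stop("`v_mV` rows must match `time_s` length", call. = FALSE)
  }
  .check_uniform(time_s)
  if (is.null(sample_rate_hz)) sample_rate_hz <- 1 / stats::median(diff(time_s))
  if (sample_rate_hz <= 0) stop("`sample_rate_hz` must be positive", call. = FALSE)
  if (!is.null(ttl_pulse_times_s)) {
    rng <- range(time_s)
    if (any(ttl_pulse_times_s < rng[1] | ttl_pulse_times_s > rng[2])) {
      stop("TTL pulse times must lie within the trace time span", call. = FALSE)
    }
  }
  colnames(v_mV) <- c("ch1_mV", "ch2_mV")
  structure(
    list(time_s = time_s, v_mV = v_mV, sample_rate_hz = sample_rate_hz,
         ttl_pulse_times_s = ttl_pulse_times_s),
    class = "sensor_trace"
  )
}

#' Sinusoidal stimulus trace
#'
#' Position and velocity of a sinusoidal vestibular or visual stimulus.
#' Velocity is the analytic derivative of position.
#'
#' @param time_s Uniform sample times (s).
#' @param position_deg Stimulus position (deg).
#' @param velocity_deg_s Stimulus velocity (deg/s).
#' @param frequency_hz Stimulus frequency (Hz).
#' @param peak_velocity_deg_s Peak velocity (deg/s).
#' @return An object of class `stimulus_trace`.
#' @export
stimulus_trace <- function(time_s, position_deg, velocity_deg_s,
                           frequency_hz, peak_velocity_deg_s) {
  n <- length(time_s)
  if (length(position_deg) != n || length(velocity_deg_s) != n) {
    stop("stimulus fields must have equal length", call. = FALSE)
  }
  .check_uniform(time_s)
  # velocity must be the numerical derivative of position
  dt <- stats::median(diff(time_s))
  dnum <- diff(position_deg) / dt
  vmid <- (velocity_deg_s[-1] + velocity_deg_s[-n]) / 2
  tol <- max(abs(velocity_deg_s)) * 0.02 + 1e-9
  if (stats::median(abs(dnum - vmid)) > tol) {
    stop("`velocity_deg_s` is not the derivative of `position_deg`", call. = FALSE)
  }
  structure(
    list(time_s = time_s, position_deg = position_deg,
         velocity_deg_s = velocity_deg_s, frequency_hz = frequency_hz,
         peak_velocity_deg_s = peak_velocity_deg_s,
         sample_rate_hz = 1 / dt),
    class = "stimulus_trace"
  )
}

#' Velocity trace with mandatory units
#'
#' Result of [differentiate()]: per-sample velocity with the differentiation
#' window and the units of the source trace recorded.
#'
#' @param time_s Sample times (s).
#' @param value Velocity per sample.
#' @param units Unit string, e.g. `"deg/s"` or `"mV/ms"`.
#' @param window_ms Differentiation window used (ms).
#' @return An object of class `velocity_trace`.
#' @export
velocity_trace <- function(time_s, value, units, window_ms = NA_real_) {
  if (length(time_s) != length(value)) {
    stop("`time_s` and `value` must have equal length", call. = FALSE)
  }
  if (missing(units) || !nzchar(units)) {
    stop("`units` tag is mandatory for velocity traces", call. = FALSE)
  }
  structure(
    list(time_s = time_s, value = value, units = units, window_ms = window_ms,
         sample_rate_hz = 1 / stats::median(diff(time_s))),
    class = "velocity_trace"
  )
}

.check_uniform <- function(time_s, tol = 1e-6) {
  d <- diff(time_s)
  if (any(d <= 0)) stop("`time_s` must be strictly increasing", call. = FALSE)
  if ((max(d) - min(d)) > tol * stats::median(d) * 100) {
    stop("`time_s` must be uniformly sampled", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.eye_trace <- function(x, ...) {
  cat(sprintf("<eye_trace> %d samples @ %.6g Hz, %.3g-%.3g s, range [%.3g, %.3g] deg\n",
              length(x$time_s), x$sample_rate_hz, x$time_s[1],
              x$time_s[length(x$time_s)], min(x$position_deg),
              max(x$position_deg)))
  invisible(x)
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("<sensor_trace> %d samples @ %.6g Hz, 2 channels, %d TTL pulses\n",
              length(x$time_s), x$sample_rate_hz,
              length(x$ttl_pulse_times_s %||% numeric(0))))
  invisible(x)
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf("<stimulus_trace> %.3g Hz sinusoid, peak %.3g deg/s, %d samples @ %.6g Hz\n",
              x$frequency_hz, x$peak_velocity_deg_s, length(x$time_s),
              x$sample_rate_hz))
  invisible(x)
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("<velocity_trace> %d samples, units %s, window %.3g ms\n",
              length(x$time_s), x$units, x$window_ms))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
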