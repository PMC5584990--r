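# Trace conditioning: zero-phase Butterworth low-pass, sliding-window
# least-squares differentiation, velocity-threshold exclusion masks
# (desaccading), and LED-flash alignment of the video and sensor streams.

#' Zero-phase Butterworth low-pass filter
#'
#' Order-4 Butterworth applied forward-backward ([signal::filtfilt()]) for
#' zero phase: unit DC gain, -3 dB at the cutoff.
#'
#' @param x Numeric vector, [eye_trace()] or [sensor_trace()] (both
#'   channels filtered).
#' @param cutoff_hz Cutoff frequency (Hz). Default 100, the acquisition
#'   filter setting.
#' @param sample_rate_hz Required for plain numeric input.
#' @param order Filter order (default 4).
#' @return Same shape as the input.
#' @export
lowpass_filter <- function(x, cutoff_hz = 100, sample_rate_hz = NULL,
                           order = 4) {
  if (inherits(x, "eye_trace")) {
    x$position_deg <- lowpass_filter(x$position_deg, cutoff_hz,
                                     x$sample_rate_hz, order)
    return(x)
  }
  if (inherits(x, "sensor_trace")) {
    x$v_mV[, 1] <- lowpass_filter(x$v_mV[, 1], cutoff_hz, x$sample_rate_hz, order)
    x$v_mV[, 2] <- lowpass_filter(x$v_mV[, 2], cutoff_hz, x$sample_rate_hz, order)
    return(x)
  }
  if (is.null(sample_rate_hz)) stop("`sample_rate_hz` is required", call. = FALSE)
  if (cutoff_hz >= sample_rate_hz / 2) {
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  # the forward-backward pass squares the magnitude response; place the
  # design corner (in prewarped digital frequency) so the zero-phase
  # response is exactly -3 dB at `cutoff`
  design_hz <- atan(tan(pi * cutoff_hz / sample_rate_hz) /
                      (sqrt(2) - 1)^(1 / (2 * order))) *
    sample_rate_hz / pi
  design_hz <- min(design_hz, 0.99 * sample_rate_hz / 2)
  bf <- signal::butter(order, design_hz / (sample_rate_hz / 2), type = "low")
  n <- length(x)
  np <- min(n - 1, 3 * ceiling(sample_rate_hz / cutoff_hz))
  # odd reflection padding suppresses the filter's edge transients
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  as.numeric(signal::filtfilt(bf, xp))[(np + 1):(np + n)]
}

# Least-squares slope in a centered sliding window; exact on linear signals.
# Interior samples via convolution; the first/last half-window samples use
# shrunken windows.
.window_slope <- function(y, fs, window_ms, method = c("slope", "endpoint")) {
  method <- match.arg(method)
  dt <- 1 / fs
  n <- length(y)
  half <- max(1L, round(window_ms / 1000 * fs / 2))
  if (2L * half + 1L > n) stop("window longer than trace", call. = FALSE)
  if (method == "endpoint") {
    s <- c(rep(NA_real_, half),
           (y[(2 * half + 1):n] - y[1:(n - 2 * half)]) / (2 * half * dt),
           rep(NA_real_, half))
  } else {
    j <- (-half):half
    wts <- j / (dt * sum(j^2))
    interior <- stats::filter(y, rev(wts), sides = 2)
    s <- as.numeric(interior)
  }
  for (i in c(seq_len(half), (n - half + 1):n)) {  # shrunken edge windows
    lo <- max(1L, i - half); hi <- min(n, i + half)
    tt <- (lo:hi) * dt; yy <- y[lo:hi]
    s[i] <- sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }
  s
}

#' Sliding-window differentiation
#'
#' Velocity as the least-squares slope in a centered sliding window (odd
#' sample count nearest the requested width), which is exact on linear
#' signals; an endpoint-difference variant is available. Eye traces return
#' deg/s; sensor traces return a list of per-channel mV/ms traces, the
#' units of the magnet artifact threshold.
#'
#' @param trace An [eye_trace()], [sensor_trace()] or numeric vector.
#' @param window_ms Window width (ms). Default 50.
#' @param method `"slope"` (least-squares fit, default) or `"endpoint"`.
#' @param sample_rate_hz,units Required for plain numeric input.
#' @return A [velocity_trace()] (or a list of two for sensor input).
#' @export
differentiate <- function(trace, window_ms = 50,
                          method = c("slope", "endpoint"),
                          sample_rate_hz = NULL, units = NULL) {
  method <- match.arg(method)
  if (inherits(trace, "eye_trace")) {
    v <- .window_slope(trace$position_deg, trace$sample_rate_hz, window_ms, method)
    return(velocity_trace(trace$time_s, v, "deg/s", window_ms))
  }
  if (inherits(trace, "stimulus_trace")) {
    v <- .window_slope(trace$position_deg, trace$sample_rate_hz, window_ms, method)
    return(velocity_trace(trace$time_s, v, "deg/s", window_ms))
  }
  if (inherits(trace, "sensor_trace")) {
    out <- lapply(1:2, function(c) {
      v <- .window_slope(trace$v_mV[, c], trace$sample_rate_hz, window_ms, method)
      velocity_trace(trace$time_s, v / 1000, "mV/ms", window_ms)
    })
    names(out) <- c("ch1", "ch2")
    return(out)
  }
  if (is.null(sample_rate_hz) || is.null(units)) {
    stop("numeric input needs `sample_rate_hz` and `units`", call. = FALSE)
  }
  v <- .window_slope(trace, sample_rate_hz, window_ms, method)
  velocity_trace((seq_along(trace) - 1) / sample_rate_hz, v, units, window_ms)
}

#' Velocity-threshold exclusion mask (desaccading)
#'
#' Marks samples whose |velocity| exceeds the threshold, dilates each marked
#' interval by `pad_ms` on both sides and merges overlaps. The standard
#' thresholds are 50 deg/s for video-derived eye velocity and 5 mV/ms for
#' raw sensor velocity.
#'
#' @param velocity A [velocity_trace()].
#' @param threshold Threshold in the trace's units, > 0.
#' @param pad_ms Dilation on each side (ms). Default 50.
#' @param source Tag recorded on the mask (`"video"`, `"sensor"`, ...).
#' @return An `exclusion_mask`: logical vector (TRUE = excluded) with
#'   attributes `source` and `pad_ms`.
#' @export
detect_artifacts <- function(velocity, threshold, pad_ms = 50,
                             source = "unspecified") {
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  v <- velocity$value
  bad <- is.finite(v) & abs(v) > threshold
  pad_n <- round(pad_ms / 1000 * velocity$sample_rate_hz)
  if (pad_n > 0 && any(bad)) {
    idx <- which(bad)
    lo <- pmax(1L, idx - pad_n); hi <- pmin(length(v), idx + pad_n)
    out <- logical(length(v))
    for (k in seq_along(idx)) out[lo[k]:hi[k]] <- TRUE
    bad <- out
  }
  structure(bad, class = "exclusion_mask", source = source, pad_ms = pad_ms)
}

#' Union of exclusion masks
#'
#' A sample marked for removal in either the video or the sensor stream is
#' excluded from both.
#'
#' @param ... `exclusion_mask` objects (or logical vectors) of equal length.
#' @return An `exclusion_mask` tagged `"union"`.
#' @export
mask_union <- function(...) {
  ms <- list(...)
  len <- unique(vapply(ms, length, integer(1)))
  if (length(len) != 1L) stop("masks must have equal length", call. = FALSE)
  out <- Reduce(`|`, ms)
  structure(as.logical(out), class = "exclusion_mask", source = "union",
            pad_ms = max(vapply(ms, function(m) attr(m, "pad_ms") %||% 0,
                                numeric(1))))
}

#' Convert an exclusion mask to an interval table
#'
#' @param mask An `exclusion_mask`.
#' @param time_s Sample times matching the mask.
#' @return data.frame `start_s`, `end_s`, `source`.
#' @export
mask_intervals <- function(mask, time_s) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_s = time_s[starts[keep]], end_s = time_s[ends[keep]],
             source = attr(mask, "source") %||% "unspecified")
}

#' Align the video and sensor streams via LED sync flashes
#'
#' The LED flash onsets seen by the cameras and the TTL pulse times recorded
#' with the sensor mark the same physical events. Flashes are matched to TTL
#' pulses by nearest neighbour after a coarse offset from the first pair
#' (robust to single missed detections), and a linear fit of TTL time on
#' flash time gives the clock offset and drift. The video eye trace is then
#' re-expressed in sensor time and linearly interpolated (upsampled) onto
#' the sensor's sample grid. Exclusion masks from either stream are mapped
#' onto that grid and unioned, so a segment removed in either stream is
#' removed from both.
#'
#' @param video_eye An [eye_trace()] on the camera clock (typically 30 Hz).
#' @param flash_times_s Flash onset times in the camera clock (s).
#' @param sensor A [sensor_trace()].
#' @param ttl_times_s TTL pulse times in the sensor clock; defaults to the
#'   pulses stored in `sensor`.
#' @param video_mask,sensor_mask Optional `exclusion_mask`s on the two
#'   native grids.
#' @param match_tol_s Maximum |flash - TTL| after coarse offset for a pair
#'   to count as matched (s). Default 0.25.
#' @return A list of class `aligned_streams`: `time_s` (sensor grid),
#'   `eye_deg_video`, `v_mV`, `excluded`, `clock_offset_s`, `clock_drift`,
#'   `flash_residuals_s`, `n_matched`.
#' @export
align_streams <- function(video_eye, flash_times_s, sensor,
                          ttl_times_s = sensor$ttl_pulse_times_s,
                          video_mask = NULL, sensor_mask = NULL,
                          match_tol_s = 0.25) {
  if (length(flash_times_s) < 2L || length(ttl_times_s) < 2L) {
    stop("at least 2 sync flashes are required in both streams", call. = FALSE)
  }
  # With a periodic pulse train the offset is only identifiable up to the
  # pulse period: evaluate every coarse offset that pairs the first flash
  # with some TTL pulse, keep those matching the most flashes, and break
  # ties by the smallest absolute clock offset.
  cand <- ttl_times_s - flash_times_s[1]
  n_match <- vapply(cand, function(coarse) {
    j <- vapply(flash_times_s + coarse,
                function(f) which.min(abs(ttl_times_s - f)), integer(1))
    sum(abs(ttl_times_s[j] - (flash_times_s + coarse)) <= match_tol_s &
          !duplicated(j))
  }, numeric(1))
  best <- which(n_match == max(n_match))
  coarse <- cand[best[which.min(abs(cand[best]))]]
  j <- vapply(flash_times_s + coarse,
              function(f) which.min(abs(ttl_times_s - f)), integer(1))
  resid0 <- ttl_times_s[j] - (flash_times_s + coarse)
  keep <- abs(resid0) <= match_tol_s & !duplicated(j)
  if (sum(keep) < 2L) stop("fewer than 2 matched sync flashes", call. = FALSE)
  fit <- stats::lm(ttl_times_s[j][keep] ~ flash_times_s[keep])
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])

  t_video_in_sensor <- a + b * video_eye$time_s
  ts <- sensor$time_s
  eye_i <- stats::approx(t_video_in_sensor, video_eye$position_deg,
                         xout = ts)$y
  excl <- !is.finite(eye_i)
  if (!is.null(video_mask)) {
    vm <- stats::approx(t_video_in_sensor, as.numeric(video_mask), xout = ts,
                        method = "constant", rule = 2, f = 0)$y
    # a sensor sample between two video samples is excluded if either is
    vm2 <- stats::approx(t_video_in_sensor, as.numeric(video_mask), xout = ts,
                         method = "constant", rule = 2, f = 1)$y
    excl <- excl | (vm > 0) | (vm2 > 0)
  }
  if (!is.null(sensor_mask)) excl <- excl | as.logical(sensor_mask)
  structure(
    list(time_s = ts, eye_deg_video = eye_i, v_mV = sensor$v_mV,
         excluded = excl, clock_offset_s = a, clock_drift = b,
         flash_residuals_s = unname(stats::residuals(fit)),
         n_matched = sum(keep)),
    class = "aligned_streams"
  )
}

#' @export
print.aligned_streams <- function(x, ...) {
  cat(sprintf(paste0("<aligned_streams> %d samples, %d/%d excluded, ",
                     "clock offset %.4g s, drift %.6g, %d flashes matched\n"),
              length(x$time_s), sum(x$excluded), length(x$excluded),
              x$clock_offset_s, x$clock_drift, x$n_matched))
  invisible(x)
}
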