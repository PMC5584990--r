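# Forward model of the two-channel AMR angle sensor (HMC1512-style): each
# Wheatstone bridge outputs a differential voltage proportional to sin(2*theta)
# of the in-plane magnetic field angle, the two bridges rotated 45 deg apart.

# Sensitivity anchors (mV/deg, channel mean) measured at vertical magnet-sensor
# distances of 0, 3 and 5 mm on the bench; used to anchor the attenuation curve.
.SENS_ANCHOR_MM <- c(0, 3, 5)
.SENS_ANCHOR_MV_DEG <- c(224.7, 127.0, 28.1)

# Mean of |dV/dtheta| over +/-22.5 deg around a zero crossing of A*sin(2*theta)
# equals A*sqrt(2)/45; its inverse converts a mean slope into an amplitude.
.amp_from_mean_slope <- function(slope_mV_deg) slope_mV_deg * 45 / sqrt(2)
.mean_slope_from_amp <- function(amp_mV) amp_mV * sqrt(2) / 45

#' AMR sensor specification
#'
#' Parameters of the two-channel anisotropic magnetoresistive angle sensor.
#' Each channel responds as `A * sin(2 * (theta - phase_c))` plus a baseline
#' offset; the two channels are tuned 45 degrees apart.
#'
#' @param channel_phase_deg Length-2 tuning offsets (deg); must differ by 45.
#' @param peak_amplitude_mV Amplitude `A` of the sin(2 theta) response at the
#'   reference geometry (magnet directly on the sensor). The default is the
#'   amplitude whose mean zero-crossing slope equals the 0 mm bench
#'   sensitivity of 224.7 mV/deg.
#' @param baseline_offset_mV Length-2 additive offsets (mV).
#' @param noise_sd_mV Additive Gaussian noise SD per sample (mV).
#' @return An object of class `amr_sensor_spec`.
#' @export
amr_sensor_spec <- function(channel_phase_deg = c(0, 45),
                            peak_amplitude_mV = .amp_from_mean_slope(224.7),
                            baseline_offset_mV = c(0, 0),
                            noise_sd_mV = 0) {
  if (length(channel_phase_deg) != 2L) {
    stop("exactly 2 channels are required", call. = FALSE)
  }
  if (abs(abs(channel_phase_deg[2] - channel_phase_deg[1]) - 45) > 1e-9) {
    stop("channel phases must differ by 45 degrees", call. = FALSE)
  }
  if (!is.finite(peak_amplitude_mV) || peak_amplitude_mV <= 0) {
    stop("`peak_amplitude_mV` must be positive", call. = FALSE)
  }
  if (length(baseline_offset_mV) == 1L) baseline_offset_mV <- rep(baseline_offset_mV, 2)
  if (noise_sd_mV < 0) stop("`noise_sd_mV` must be non-negative", call. = FALSE)
  structure(
    list(channel_phase_deg = channel_phase_deg,
         peak_amplitude_mV = peak_amplitude_mV,
         baseline_offset_mV = baseline_offset_mV,
         noise_sd_mV = noise_sd_mV),
    class = "amr_sensor_spec"
  )
}

#' Magnet placement geometry relative to the sensor
#'
#' Describes where the implanted magnet sits relative to the sensor: vertical
#' distance from the sensor plane, in-plane offset from the sensor center,
#' tilt of the magnet's N-S axis out of the sensor plane, and the dipole
#' moment magnitude used by the point-dipole field model.
#'
#' @param vertical_distance_mm Magnet-to-sensor-plane distance (mm), >= 0.
#' @param horizontal_offset_mm In-plane offset of the sensor center from the
#'   rotation axis (mm).
#' @param tilt_deg Tilt of the magnet axis out of the sensor plane, in
#'   \[-90, 90\] degrees.
#' @param dipole_strength Point-dipole moment magnitude (arbitrary units).
#' @return An object of class `magnet_geometry`.
#' @export
magnet_geometry <- function(vertical_distance_mm = 0,
                            horizontal_offset_mm = 0,
                            tilt_deg = 0,
                            dipole_strength = 1) {
  if (vertical_distance_mm < 0) {
    stop("`vertical_distance_mm` must be non-negative", call. = FALSE)
  }
  if (horizontal_offset_mm < 0) {
    stop("`horizontal_offset_mm` must be non-negative", call. = FALSE)
  }
  if (tilt_deg < -90 || tilt_deg > 90) {
    stop("`tilt_deg` must lie in [-90, 90]", call. = FALSE)
  }
  structure(
    list(vertical_distance_mm = vertical_distance_mm,
         horizontal_offset_mm = horizontal_offset_mm,
         tilt_deg = tilt_deg, dipole_strength = dipole_strength),
    class = "magnet_geometry"
  )
}

#' Two-channel AMR response to a magnet angle
#'
#' Channel `c` returns `A * sin(2 * (theta_m - phase_c)) + offset_c`. The
#' response is 180-degree periodic in the magnet angle, the defining property
#' of an AMR bridge (it senses field axis, not polarity).
#'
#' @param theta_m Magnet angle(s) in degrees. Finite.
#' @param spec An [amr_sensor_spec()].
#' @param amplitude_mV Optional amplitude override (mV), e.g. the output of
#'   [sensitivity_profile()] for a displaced magnet.
#' @return A numeric matrix, one row per angle, columns `ch1_mV`, `ch2_mV`.
#' @examples
#' amr_response(22.5, amr_sensor_spec(peak_amplitude_mV = 1000))
#' @export
amr_response <- function(theta_m, spec = amr_sensor_spec(),
                         amplitude_mV = spec$peak_amplitude_mV) {
  if (!all(is.finite(theta_m))) {
    stop("`theta_m` must be finite", call. = FALSE)
  }
  out <- vapply(1:2, function(c) {
    amplitude_mV *
      sin(2 * (theta_m - spec$channel_phase_deg[c]) * pi / 180) +
      spec$baseline_offset_mV[c]
  }, numeric(length(theta_m)))
  out <- matrix(out, ncol = 2, dimnames = list(NULL, c("ch1_mV", "ch2_mV")))
  out
}

#' Effective response amplitude for a displaced magnet
#'
#' Scales the reference amplitude by a monotone non-increasing attenuation in
#' both the vertical magnet-sensor distance and the horizontal offset. The
#' vertical curve is a monotone piecewise-cubic interpolant anchored so that
#' the mean zero-crossing sensitivities at 0, 3 and 5 mm equal 224.7, 127.0
#' and 28.1 mV/deg (constant beyond 5 mm). The horizontal factor follows the
#' inverse-cube falloff of a dipole field about a 3 mm reference depth.
#' Magnet tilt does not enter: the AMR bridges run in magnetic saturation and
#' respond to field direction, not magnitude.
#'
#' @param geometry A [magnet_geometry()].
#' @param spec An [amr_sensor_spec()].
#' @return Effective peak amplitude (mV), scalar.
#' @export
sensitivity_profile <- function(geometry, spec = amr_sensor_spec()) {
  if (!inherits(geometry, "magnet_geometry")) {
    stop("`geometry` must be a magnet_geometry", call. = FALSE)
  }
  dv <- geometry$vertical_distance_mm
  dh <- geometry$horizontal_offset_mm
  att_v <- .vertical_attenuation(dv)
  d0 <- 3  # mm, reference depth for the horizontal falloff
  att_h <- (d0^2 / (d0^2 + dh^2))^(3 / 2)
  spec$peak_amplitude_mV * att_v * att_h
}

.vertical_attenuation <- local({
  fn <- NULL
  function(dv) {
    if (is.null(fn)) {
      fn <<- stats::splinefun(.SENS_ANCHOR_MM,
                              .SENS_ANCHOR_MV_DEG / .SENS_ANCHOR_MV_DEG[1],
                              method = "hyman")
    }
    fn(pmin(dv, max(.SENS_ANCHOR_MM)))
  }
})

#' In-plane field angle of a rotating point dipole at the sensor
#'
#' Models the magnet as a point dipole riding the eye's rotation: the dipole
#' sits at `lever_arm_mm` from the rotation axis in the rotation plane, its
#' moment pointing along the magnet angle (tilted out of plane by
#' `geometry$tilt_deg`). The sensor center sits at
#' `(horizontal_offset_mm, 0, vertical_distance_mm)` relative to the axis.
#' Returns the angle of the in-plane field components at the sensor, in
#' degrees mod 360. For a centered magnet (zero offsets) this is
#' `theta_m + 180`: the on-axis dipole field is antiparallel to the in-plane
#' moment.
#'
#' @param geometry A [magnet_geometry()].
#' @param theta_m Magnet angle(s), degrees.
#' @param lever_arm_mm Distance of the dipole from the rotation axis (mm).
#' @return Field angle(s) in degrees, in \[0, 360).
#' @export
dipole_field_angle <- function(geometry, theta_m, lever_arm_mm = 0) {
  th <- theta_m * pi / 180
  tau <- geometry$tilt_deg * pi / 180
  # dipole position and moment rotate with the eye
  px <- lever_arm_mm * cos(th); py <- lever_arm_mm * sin(th)
  mx <- cos(tau) * cos(th); my <- cos(tau) * sin(th); mz <- sin(tau)
  sx <- geometry$horizontal_offset_mm; sy <- 0
  sz <- geometry$vertical_distance_mm
  rx <- sx - px; ry <- sy - py; rz <- sz
  r2 <- rx^2 + ry^2 + rz^2
  if (any(r2 < 1e-12)) {
    stop("sensor coincides with the dipole location", call. = FALSE)
  }
  r <- sqrt(r2)
  ux <- rx / r; uy <- ry / r; uz <- rz / r
  mdotu <- mx * ux + my * uy + mz * uz
  s <- geometry$dipole_strength / r^3
  bx <- s * (3 * ux * mdotu - mx)
  by <- s * (3 * uy * mdotu - my)
  (atan2(by, bx) * 180 / pi) %% 360
}

#' Simulate a sensor voltage trace from an eye trace
#'
#' Composes [amr_response()] over an eye-angle trace: the magnet angle is the
#' eye angle plus a mounting offset, the response amplitude comes from
#' [sensitivity_profile()] for the given geometry, and seeded Gaussian noise
#' of SD `spec$noise_sd_mV` is added per channel. Optionally embeds a 1 Hz
#' TTL sync-pulse train.
#'
#' @param eye An [eye_trace()].
#' @param spec An [amr_sensor_spec()].
#' @param geometry A [magnet_geometry()].
#' @param mounting_offset_deg Angular offset between eye angle and magnet
#'   angle introduced by surgical placement (deg, default 0).
#' @param ttl_hz Rate of the embedded TTL pulse train (Hz); `NULL` for none.
#' @param seed Integer seed for the noise; `NULL` uses the current RNG state.
#' @return A [sensor_trace()].
#' @export
simulate_sensor_trace <- function(eye, spec = amr_sensor_spec(),
                                  geometry = magnet_geometry(vertical_distance_mm = 3),
                                  mounting_offset_deg = 0,
                                  ttl_hz = 1, seed = NULL) {
  if (!inherits(eye, "eye_trace")) stop("`eye` must be an eye_trace", call. = FALSE)
  if (length(eye$time_s) == 0L) stop("empty eye trace", call. = FALSE)
  amp <- sensitivity_profile(geometry, spec)
  v <- amr_response(eye$position_deg + mounting_offset_deg, spec,
                    amplitude_mV = amp)
  add_noise <- function() {
    if (spec$noise_sd_mV > 0) {
      v + matrix(stats::rnorm(length(v), sd = spec$noise_sd_mV), ncol = 2)
    } else v
  }
  v <- if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())
  ttl <- NULL
  if (!is.null(ttl_hz) && ttl_hz > 0) {
    ttl <- seq(eye$time_s[1], eye$time_s[length(eye$time_s)], by = 1 / ttl_hz)
  }
  sensor_trace(eye$time_s, v, sample_rate_hz = eye$sample_rate_hz,
               ttl_pulse_times_s = ttl)
}

#' Sensitivity of a sensor channel from an angle sweep
#'
#' Estimates each channel's sensitivity (mV/deg) the way it is measured on
#' the bench: locate the zero crossings of the channel's output over the
#' sweep, compute the local slope of voltage vs angle, and average its
#' absolute value within +/-22.5 degrees of each crossing, then across
#' crossings. For an ideal `A*sin(2 theta)` channel the result is
#' `A*sqrt(2)/45`.
#'
#' @param angle_sweep Strictly monotone magnet angles (deg).
#' @param voltage_sweep Voltages (mV): a vector (one channel) or a matrix
#'   with one column per channel.
#' @param half_range_deg Averaging half-range around each crossing (deg).
#' @param slope_window_deg `NULL` for centered finite differences (dense,
#'   noise-free sweeps); otherwise the half-width (deg) of a least-squares
#'   slope window for noisy sweeps.
#' @return Numeric vector, one sensitivity per channel (mV/deg); `NA` for a
#'   channel with no zero crossing in the sweep (not estimable).
#' @examples
#' th <- seq(-45, 45, by = 0.1)
#' estimate_sensitivity(th, 1000 * sin(2 * th * pi / 180))  # ~ 1000*sqrt(2)/45
#' @export
estimate_sensitivity <- function(angle_sweep, voltage_sweep,
                                 half_range_deg = 22.5,
                                 slope_window_deg = NULL) {
  d <- diff(angle_sweep)
  if (any(d <= 0) && any(d >= 0) && !(all(d > 0) || all(d < 0))) {
    stop("`angle_sweep` must be strictly monotone", call. = FALSE)
  }
  if (all(d < 0)) {  # normalize direction
    angle_sweep <- rev(angle_sweep)
    voltage_sweep <- if (is.matrix(voltage_sweep)) {
      voltage_sweep[rev(seq_len(nrow(voltage_sweep))), , drop = FALSE]
    } else rev(voltage_sweep)
  }
  vm <- if (is.matrix(voltage_sweep)) voltage_sweep else cbind(voltage_sweep)
  if (nrow(vm) != length(angle_sweep)) {
    stop("sweep lengths must match", call. = FALSE)
  }
  vapply(seq_len(ncol(vm)), function(c) {
    .channel_sensitivity(angle_sweep, vm[, c], half_range_deg, slope_window_deg)
  }, numeric(1))
}

.channel_sensitivity <- function(theta, v, half_range, window) {
  s <- sign(v)
  cross <- which(s[-1] * s[-length(s)] < 0 | (s[-length(s)] == 0))
  # crossing angles by linear interpolation (exact zeros use the grid point)
  zc <- vapply(cross, function(i) {
    if (v[i] == 0) return(theta[i])
    theta[i] + (theta[i + 1] - theta[i]) * (0 - v[i]) / (v[i + 1] - v[i])
  }, numeric(1))
  if (length(zc) == 0L) return(NA_real_)
  slope <- .local_slope(theta, v, window)
  per_crossing <- vapply(zc, function(z) {
    idx <- which(abs(theta - z) <= half_range)
    if (length(idx) < 2L) return(NA_real_)
    mean(abs(slope[idx]), na.rm = TRUE)
  }, numeric(1))
  mean(per_crossing, na.rm = TRUE)
}

.local_slope <- function(theta, v, window) {
  n <- length(v)
  if (is.null(window)) {
    # centered finite differences, one-sided at the ends
    s <- numeric(n)
    s[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (theta[3:n] - theta[1:(n - 2)])
    s[1] <- (v[2] - v[1]) / (theta[2] - theta[1])
    s[n] <- (v[n] - v[n - 1]) / (theta[n] - theta[n - 1])
    s
  } else {
    vapply(seq_len(n), function(i) {
      idx <- which(abs(theta - theta[i]) <= window)
      if (length(idx) < 2L) return(NA_real_)
      th <- theta[idx] - mean(theta[idx]); vv <- v[idx] - mean(v[idx])
      sum(th * vv) / sum(th^2)
    }, numeric(1))
  }
}
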