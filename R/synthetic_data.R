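# Synthetic oculomotor sessions with known ground truth: sinusoidal
# vestibular stimulus, eye response with specified gain/phase plus saccades
# and fixation jitter, AMR sensor voltages, dual-camera pupil/CR landmarks,
# rendered eye frames, overhead body-motion video, and 1 Hz LED sync flashes.

#' Ground-truth eye kinematics specification
#'
#' Parameterizes the synthetic eye response that the calibration and
#' analysis pipeline must recover.
#'
#' @param response_gain Eye/stimulus velocity amplitude ratio (>= 0).
#'   Default 0.8, a typical compensatory response to vestibular rotation in
#'   the light.
#' @param response_phase_deg Phase relative to the ideal compensatory
#'   response (deg; positive = phase lead). Default 0.
#' @param saccade_rate_hz Poisson rate of saccades (Hz). Default 0.2.
#' @param saccade_amplitude_deg Length-2 `(mean, SD)` of saccade amplitude
#'   (deg). Default `c(5, 1.5)`.
#' @param saccade_centering_prob Probability that a saccade is directed
#'   back toward the central position, mimicking the re-centering quick
#'   phases of fixating mice so that eye position stays bounded. Default
#'   0.8.
#' @param fixation_jitter_sd_deg SD of white positional jitter (deg).
#'   Default 0.02.
#' @param sample_rate_hz Output sampling rate (Hz). Default 1000.
#' @return An object of class `eye_kinematics_spec`.
#' @export
eye_kinematics_spec <- function(response_gain = 0.8,
                                response_phase_deg = 0,
                                saccade_rate_hz = 0.2,
                                saccade_amplitude_deg = c(5, 1.5),
                                saccade_centering_prob = 0.8,
                                fixation_jitter_sd_deg = 0.02,
                                sample_rate_hz = 1000) {
  if (response_gain < 0) stop("`response_gain` must be >= 0", call. = FALSE)
  if (fixation_jitter_sd_deg < 0) stop("jitter SD must be >= 0", call. = FALSE)
  if (saccade_rate_hz < 0) stop("`saccade_rate_hz` must be >= 0", call. = FALSE)
  if (sample_rate_hz <= 0) stop("`sample_rate_hz` must be positive", call. = FALSE)
  structure(
    list(response_gain = response_gain,
         response_phase_deg = response_phase_deg,
         saccade_rate_hz = saccade_rate_hz,
         saccade_amplitude_deg = saccade_amplitude_deg,
         saccade_centering_prob = saccade_centering_prob,
         fixation_jitter_sd_deg = fixation_jitter_sd_deg,
         sample_rate_hz = sample_rate_hz),
    class = "eye_kinematics_spec"
  )
}

#' Sinusoidal stimulus generator
#'
#' Velocity `peak * sin(2 pi f t)`; position is its integral,
#' `-(peak / (2 pi f)) * cos(2 pi f t)`, shifted to zero mean.
#'
#' @param frequency_hz Stimulus frequency (Hz), one of 0.2, 0.5, 1, 2, 5 in
#'   the standard battery; any positive value is accepted.
#' @param peak_velocity_deg_s Peak velocity (deg/s). Default 10.
#' @param duration_s Duration (s).
#' @param sample_rate_hz Sampling rate (Hz). Default 1000.
#' @return A [stimulus_trace()].
#' @export
generate_stimulus <- function(frequency_hz, peak_velocity_deg_s = 10,
                              duration_s = 60, sample_rate_hz = 1000) {
  if (frequency_hz <= 0) stop("`frequency_hz` must be positive", call. = FALSE)
  if (peak_velocity_deg_s <= 0 || duration_s <= 0 || sample_rate_hz <= 0) {
    stop("all stimulus arguments must be positive", call. = FALSE)
  }
  n <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  w <- 2 * pi * frequency_hz
  vel <- peak_velocity_deg_s * sin(w * t)
  pos <- -(peak_velocity_deg_s / w) * cos(w * t)
  pos <- pos - mean(pos)
  stimulus_trace(t, pos, vel, frequency_hz, peak_velocity_deg_s)
}

#' Ground-truth eye trace for a stimulus
#'
#' Slow-phase eye velocity is `-gain` times the stimulus velocity shifted by
#' the response phase (so gain 1 / phase 0 is perfectly compensatory),
#' integrated to position. Saccades arrive as a Poisson process and are added
#' as rapid 20 ms linear-ramp steps; white fixation jitter is added to
#' position. Deterministic given `seed`.
#'
#' @param stimulus A [stimulus_trace()].
#' @param spec An [eye_kinematics_spec()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An [eye_trace()] at `spec$sample_rate_hz`.
#' @export
generate_eye_trace <- function(stimulus, spec = eye_kinematics_spec(),
                               seed = NULL) {
  if (spec$sample_rate_hz < 20 * stimulus$frequency_hz) {
    stop("sample rate must be at least 20x the stimulus frequency", call. = FALSE)
  }
  fs <- spec$sample_rate_hz
  dur <- length(stimulus$time_s) / stimulus$sample_rate_hz
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  w <- 2 * pi * stimulus$frequency_hz
  phi <- spec$response_phase_deg * pi / 180
  g <- spec$response_gain
  # velocity = -g * peak * sin(w t + phi); position is its integral, zero-mean
  pos <- g * (stimulus$peak_velocity_deg_s / w) * cos(w * t + phi)
  pos <- pos - mean(pos)

  build <- function() {
    n_sac <- stats::rpois(1, spec$saccade_rate_hz * dur)
    sac <- numeric(n)
    if (n_sac > 0) {
      onset <- sort(stats::runif(n_sac, 0, dur))
      size <- abs(stats::rnorm(n_sac, spec$saccade_amplitude_deg[1],
                               spec$saccade_amplitude_deg[2]))
      recenter <- stats::runif(n_sac) < spec$saccade_centering_prob
      ramp_n <- max(1L, round(0.020 * fs))
      offset <- 0  # running fixation offset; re-centering saccades bound it
      for (k in seq_len(n_sac)) {
        dir <- if (recenter[k] && offset != 0) -sign(offset) else {
          sample(c(-1, 1), 1)
        }
        amp <- dir * size[k]
        offset <- offset + amp
        i0 <- findInterval(onset[k], t)
        idx <- i0:min(n, i0 + ramp_n)
        sac[idx] <- sac[idx] + amp * seq(0, 1, length.out = length(idx))
        if (max(idx) < n) sac[(max(idx) + 1):n] <- sac[(max(idx) + 1):n] + amp
      }
    }
    jit <- if (spec$fixation_jitter_sd_deg > 0) {
      stats::rnorm(n, sd = spec$fixation_jitter_sd_deg)
    } else 0
    pos + sac + jit
  }
  p <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  eye_trace(t, p, sample_rate_hz = fs)
}

#' Project an eye trace into dual-camera pupil/CR landmarks
#'
#' Forward model of the dual-angle rig in the symmetric-zero convention:
#' eye angle 0 lies on the bisector of the camera axes, so
#' `theta2 = eye + alpha/2` and `theta1 = alpha - theta2`. Pupil-CR
#' distances follow [forward_deltas()], are converted to pixels by the rig's
#' scale and resampled to the camera frame rate. The CR sits at each
#' camera's image center; the pupil landmark sits at CR + delta; both get
#' seeded Gaussian pixel noise. Frames where the eye leaves the validity
#' range are flagged, not clipped.
#'
#' The landmark timestamps are expressed in the camera's own clock, which
#' lags the sensor clock by `camera_latency_s` (frame at camera time `u`
#' shows the eye at sensor time `u + camera_latency_s`).
#'
#' @param eye An [eye_trace()] (sensor clock).
#' @param rig A [camera_rig()].
#' @param r_p_mm Pupil-plane to corneal-curvature-center distance (mm).
#' @param pixel_noise_sd Landmark noise SD (px).
#' @param frame_rate_hz Camera frame rate (Hz), default 30.
#' @param camera_latency_s Camera clock lag behind the sensor clock (s).
#' @param image_size `c(width, height)` in px; CRs at the image center.
#' @param seed Integer seed for the pixel noise.
#' @return A [pupil_frames()] data.frame with rows for both cameras.
#' @export
project_to_cameras <- function(eye, rig = camera_rig(), r_p_mm = 1.25,
                               pixel_noise_sd = 0, frame_rate_hz = 30,
                               camera_latency_s = 0,
                               image_size = c(240, 180), seed = NULL) {
  if (r_p_mm <= 0) stop("`r_p_mm` must be positive", call. = FALSE)
  a <- rig$inter_camera_angle_deg
  t_end <- eye$time_s[length(eye$time_s)]
  cam_t <- seq(0, t_end - camera_latency_s, by = 1 / frame_rate_hz)
  cam_t <- cam_t[cam_t + camera_latency_s >= eye$time_s[1]]
  ang <- stats::approx(eye$time_s, eye$position_deg,
                       xout = cam_t + camera_latency_s)$y
  valid <- ang > -a & ang < 2 * a  # both theta angles defined
  th2 <- ang + a / 2
  d <- forward_deltas(th2, r_p_mm, rig)
  dpx <- d / rig$pixel_scale_mm_per_px
  cx <- (image_size[1] + 1) / 2; cy <- (image_size[2] + 1) / 2
  nf <- length(cam_t)
  mk <- function(cam, delta_px) {
    data.frame(time_s = cam_t, cam = cam,
               pupil_x_px = cx + delta_px, pupil_y_px = cy,
               cr_x_px = cx, cr_y_px = cy, valid = valid)
  }
  df <- rbind(mk(1L, dpx[, 1]), mk(2L, dpx[, 2]))
  if (pixel_noise_sd > 0) {
    addn <- function() {
      for (col in c("pupil_x_px", "pupil_y_px", "cr_x_px", "cr_y_px")) {
        df[[col]] <- df[[col]] + stats::rnorm(nrow(df), sd = pixel_noise_sd)
      }
      df
    }
    df <- if (is.null(seed)) addn() else withr::with_seed(seed, addn())
  }
  pupil_frames(df, rig)
}

#' Rendering parameters for synthetic eye frames
#'
#' @param image_size `c(width, height)` px.
#' @param pupil_axes_px Semi-axes of the pupil ellipse (px).
#' @param pupil_angle_deg Ellipse orientation (deg).
#' @param pupil_value,iris_value Gray levels in \[0, 1\] of the pupil disc
#'   and the surrounding iris.
#' @param cr_sigma_px SD of the Gaussian corneal-reflection blobs (px).
#' @param cr_peak Brightness of a CR blob at its center. The glint is
#'   composited over the scene (a specular reflection on the cornea stays
#'   bright even in front of the dark pupil).
#' @param distractor_offset_px Horizontal offset of the opposite-LED
#'   distractor reflection CR' from the reference CR (px); 0 disables it.
#' @param noise_sd Per-pixel Gaussian noise SD (gray levels).
#' @return An object of class `eye_image_spec`.
#' @export
eye_image_spec <- function(image_size = c(240, 180),
                           pupil_axes_px = c(26, 20),
                           pupil_angle_deg = 0,
                           pupil_value = 0.08, iris_value = 0.45,
                           cr_sigma_px = 2.2, cr_peak = 0.95,
                           distractor_offset_px = 40,
                           noise_sd = 0.01) {
  structure(
    list(image_size = image_size, pupil_axes_px = pupil_axes_px,
         pupil_angle_deg = pupil_angle_deg, pupil_value = pupil_value,
         iris_value = iris_value, cr_sigma_px = cr_sigma_px,
         cr_peak = cr_peak, distractor_offset_px = distractor_offset_px,
         noise_sd = noise_sd),
    class = "eye_image_spec"
  )
}

#' Render grayscale eye frames from landmark positions
#'
#' For each frame of each camera: a mid-gray iris background, a dark filled
#' ellipse (soft, anti-aliased edge) at the pupil landmark, a bright
#' Gaussian blob at the own-camera reference CR, and a second, displaced
#' distractor blob CR' mimicking the reflection of the opposite camera's
#' LED. Seeded pixel noise is added last. Pixel (1, 1) is the top-left
#' pixel center; images are `height x width` matrices in \[0, 1\].
#'
#' @param frames A [pupil_frames()] series.
#' @param image_spec An [eye_image_spec()].
#' @param seed Integer seed for the pixel noise.
#' @return A list with elements `cam1` and `cam2`, each a list of image
#'   matrices, plus `time_s`.
#' @export
render_eye_frames <- function(frames, image_spec = eye_image_spec(),
                              seed = NULL) {
  run <- function() {
    out <- list(cam1 = list(), cam2 = list())
    for (cam in 1:2) {
      fc <- frames[frames$cam == cam, ]
      out[[cam]] <- lapply(seq_len(nrow(fc)), function(i) {
        .render_eye_frame(fc$pupil_x_px[i], fc$pupil_y_px[i],
                          fc$cr_x_px[i], fc$cr_y_px[i], image_spec)
      })
    }
    out$time_s <- sort(unique(frames$time_s))
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.render_eye_frame <- function(px, py, crx, cry, spec) {
  w <- spec$image_size[1]; h <- spec$image_size[2]
  ax <- spec$pupil_axes_px[1]; ay <- spec$pupil_axes_px[2]
  if (px - ax < 1 || px + ax > w || py - ay < 1 || py + ay > h) {
    stop("pupil ellipse exceeds the image bounds", call. = FALSE)
  }
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  th <- spec$pupil_angle_deg * pi / 180
  dx <- xs - px; dy <- ys - py
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  r <- sqrt((u / ax)^2 + (v / ay)^2)
  # soft edge ~1 px wide for sub-pixel localization
  edge_w <- 1 / mean(c(ax, ay))
  cov <- pmin(1, pmax(0, (1 - r) / edge_w + 0.5))
  img <- spec$iris_value + (spec$pupil_value - spec$iris_value) * cov
  blob <- function(img, cx, cy) {
    g <- exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * spec$cr_sigma_px^2))
    img * (1 - g) + spec$cr_peak * g
  }
  img <- blob(img, crx, cry)
  if (spec$distractor_offset_px != 0) {
    img <- blob(img, crx - spec$distractor_offset_px, cry)
  }
  if (spec$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(w * h, sd = spec$noise_sd), nrow = h)
  }
  pmin(pmax(img, 0), 1)
}

#' Synthetic overhead body-motion video
#'
#' A bright blob (the animal) performs a random walk whose per-frame
#' displacement SD follows a step schedule of activity levels, over a static
#' textured background with per-frame sensor noise. Ground-truth labels are
#' recorded per frame.
#'
#' @param activity_schedule data.frame with columns `duration_s`,
#'   `displacement_sd_px` and `label` — a step function of activity.
#' @param frame_shape `c(width, height)` px. Default `c(64, 64)`.
#' @param frame_rate_hz Frames per second. Default 15.
#' @param noise_sd Per-pixel sensor noise SD. Default 0.01.
#' @param seed Integer seed.
#' @return A list: `frames` (list of matrices), `time_s`, `labels`
#'   (character per frame), `frame_rate_hz`.
#' @export
generate_overhead_motion <- function(activity_schedule,
                                     frame_shape = c(64, 64),
                                     frame_rate_hz = 15,
                                     noise_sd = 0.01, seed = NULL) {
  stopifnot(all(c("duration_s", "displacement_sd_px", "label") %in%
                  names(activity_schedule)))
  w <- frame_shape[1]; h <- frame_shape[2]
  n_per <- round(activity_schedule$duration_s * frame_rate_hz)
  sds <- rep(activity_schedule$displacement_sd_px, n_per)
  labels <- rep(as.character(activity_schedule$label), n_per)
  n <- length(sds)
  run <- function() {
    bg <- matrix(0.2, nrow = h, ncol = w) +
      outer(seq_len(h), seq_len(w), function(i, j) 0.001 * (i + j)) +
      matrix(stats::rnorm(w * h, sd = 0.02), nrow = h)  # static texture
    xs <- matrix(rep(seq_len(w), each = h), nrow = h)
    ys <- matrix(rep(seq_len(h), times = w), nrow = h)
    pos <- c(w / 2, h / 2)
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      if (sds[i] > 0) pos <- pos + stats::rnorm(2, sd = sds[i])
      pos[1] <- min(max(pos[1], 8), w - 7)
      pos[2] <- min(max(pos[2], 8), h - 7)
      img <- bg + 0.6 * exp(-((xs - pos[1])^2 + (ys - pos[2])^2) / (2 * 4^2))
      if (noise_sd > 0) {
        img <- img + matrix(stats::rnorm(w * h, sd = noise_sd), nrow = h)
      }
      frames[[i]] <- pmin(pmax(img, 0), 1)
    }
    frames
  }
  frames <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(frames = frames, time_s = (seq_len(n) - 1) / frame_rate_hz,
       labels = labels, frame_rate_hz = frame_rate_hz)
}

#' Generate a complete synthetic session
#'
#' Composes the generators into a session bundle: stimulus, ground-truth eye
#' trace, AMR sensor voltages with a 1 Hz TTL pulse train, dual-camera
#' landmarks (camera clock lagging the sensor clock by `camera_latency_s`),
#' and the per-frame mean-intensity series of the eye cameras with 30 ms LED
#' sync flashes embedded at the TTL times. The stored ground-truth
#' calibration factor `k_true` (deg/mV) is the reciprocal small-angle
#' sensitivity of the simulated sensor channel.
#'
#' @param duration_s Session length (s). Default 60.
#' @param frequency_hz Stimulus frequency (Hz). Default 1.
#' @param peak_velocity_deg_s Stimulus peak velocity (deg/s). Default 10.
#' @param kinematics An [eye_kinematics_spec()].
#' @param sensor_spec An [amr_sensor_spec()].
#' @param geometry A [magnet_geometry()]; default 3 mm vertical distance,
#'   the typical implant depth.
#' @param rig A [camera_rig()].
#' @param r_p_mm Pupil-to-corneal-curvature-center distance (mm).
#' @param pixel_noise_sd Landmark noise SD (px). Default 0.15, the
#'   empirical sub-pixel precision of the package's own landmark detector
#'   on rendered frames.
#' @param camera_latency_s Camera clock lag (s). Default 0.
#' @param flash_hz,flash_duration_s LED sync flash rate and duration.
#' @param include_camera Generate camera landmark and intensity streams.
#' @param seed Integer seed driving every stochastic component.
#' @return An object of class `session_bundle`.
#' @export
generate_session <- function(duration_s = 60, frequency_hz = 1,
                             peak_velocity_deg_s = 10,
                             kinematics = eye_kinematics_spec(),
                             sensor_spec = amr_sensor_spec(noise_sd_mV = 5),
                             geometry = magnet_geometry(vertical_distance_mm = 3),
                             rig = camera_rig(), r_p_mm = 1.25,
                             pixel_noise_sd = 0.15,
                             camera_latency_s = 0,
                             flash_hz = 1, flash_duration_s = 0.03,
                             include_camera = TRUE, seed = 1L) {
  stim <- generate_stimulus(frequency_hz, peak_velocity_deg_s, duration_s,
                            kinematics$sample_rate_hz)
  eye <- generate_eye_trace(stim, kinematics, seed = seed)
  sensor <- simulate_sensor_trace(eye, sensor_spec, geometry,
                                  ttl_hz = flash_hz, seed = seed + 1L)
  amp <- sensitivity_profile(geometry, sensor_spec)
  k_true <- 90 / (pi * amp)  # reciprocal small-angle slope of channel 1

  camera <- NULL; cam_intensity <- NULL
  if (include_camera) {
    camera <- project_to_cameras(eye, rig, r_p_mm, pixel_noise_sd,
                                 frame_rate_hz = 30,
                                 camera_latency_s = camera_latency_s,
                                 seed = seed + 2L)
    cam_t <- sort(unique(camera$time_s))
    base <- 0.40
    inten <- withr::with_seed(seed + 3L,
                              base + stats::rnorm(length(cam_t), sd = 0.005))
    flash_cam <- sensor$ttl_pulse_times_s - camera_latency_s
    frame_dur <- 1 / 30
    for (f in flash_cam) {
      hit <- which(cam_t + frame_dur > f & cam_t < f + flash_duration_s)
      inten[hit] <- inten[hit] + 0.3
    }
    cam_intensity <- data.frame(time_s = cam_t, mean_intensity = inten)
  }
  structure(
    list(truth = list(eye = eye, k_true = k_true, kinematics = kinematics,
                      camera_latency_s = camera_latency_s),
         stimulus = stim, sensor = sensor, camera = camera,
         camera_intensity = cam_intensity,
         rig = rig, r_p_mm = r_p_mm, geometry = geometry,
         sensor_spec = sensor_spec, seed = seed),
    class = "session_bundle"
  )
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf(paste0("<session_bundle> %.3g s @ %.4g Hz stimulus, ",
                     "k_true = %.5g deg/mV, seed %d\n"),
              x$stimulus$time_s[length(x$stimulus$time_s)] +
                1 / x$stimulus$sample_rate_hz,
              x$stimulus$frequency_hz, x$truth$k_true, x$seed))
  invisible(x)
}
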