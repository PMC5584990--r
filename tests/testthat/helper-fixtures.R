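# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# standard 60 s, 1 Hz, +/-10 deg/s calibration session with noise
noisy_session <- function() {
  cached("noisy_session", generate_session(seed = 101))
}

# same conditions, every noise source disabled
clean_session <- function() {
  cached("clean_session", generate_session(
    seed = 102,
    kinematics = eye_kinematics_spec(saccade_rate_hz = 0,
                                     fixation_jitter_sd_deg = 0),
    sensor_spec = amr_sensor_spec(noise_sd_mV = 0),
    pixel_noise_sd = 0))
}

video_eye_of <- function(session, key) {
  cached(key, eye_position_from_frames(session$camera))
}

# dual-camera landmark table for a sweep of eye angles (one frame each)
sweep_frames <- function(angles, rig = camera_rig(), r_p_mm = 1.25) {
  th2 <- angles + rig$inter_camera_angle_deg / 2
  dpx <- forward_deltas(th2, r_p_mm, rig) / rig$pixel_scale_mm_per_px
  ts <- seq_along(angles) / 30
  cx <- 120.5; cy <- 90.5
  pupil_frames(rbind(
    data.frame(time_s = ts, cam = 1L, pupil_x_px = cx + dpx[, 1],
               pupil_y_px = cy, cr_x_px = cx, cr_y_px = cy, valid = TRUE),
    data.frame(time_s = ts, cam = 2L, pupil_x_px = cx + dpx[, 2],
               pupil_y_px = cy, cr_x_px = cx, cr_y_px = cy, valid = TRUE)),
    rig)
}

# rendered sweep and its detected landmarks (the expensive image fixture)
detected_sweep <- function() {
  cached("detected_sweep", {
    rig <- camera_rig()
    angles <- seq(-25, 25, by = 2.5)
    fr <- sweep_frames(angles, rig)
    rend <- render_eye_frames(fr, eye_image_spec(), seed = 7)
    det <- detect_landmarks(rend, rig)
    list(angles = angles, rig = rig, frames = fr, rendered = rend,
         detected = det)
  })
}

# constructed aligned eye/sensor vectors with a known linear map
make_aligned <- function(n = 2000, k = 0.005, offset = 1, noise_m2 = TRUE,
                         seed = 21) {
  withr::with_seed(seed, {
    m1 <- 200 * sin(2 * pi * (1:n) / 500)
    m2 <- if (noise_m2) rnorm(n, sd = 10) else m1 + rnorm(n, sd = 1)
    e <- k * m1 + offset
    list(e = e, m = cbind(m1, m2))
  })
}

# voltage sweep through the dipole field model at a given geometry: the
# field angle comes from the point-dipole model and the response amplitude
# from the geometry's attenuation profile
dipole_sweep_sensitivity <- function(geometry, lever_arm_mm = 0,
                                     spec = amr_sensor_spec()) {
  th <- seq(-45, 45, by = 0.1)
  phi <- dipole_field_angle(geometry, th, lever_arm_mm)
  v <- amr_response(phi, spec,
                    amplitude_mV = sensitivity_profile(geometry, spec))
  estimate_sensitivity(th, v)
}
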