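test_that("generate_stimulus integrates velocity into position", {
  st <- generate_stimulus(1, 10, 10, 1000)
  expect_length(st$time_s, 10000)
  expect_equal(max(abs(st$position_deg)), 10 / (2 * pi), tolerance = 1e-3)
  # velocity starts at 0 and rises
  st2 <- generate_stimulus(0.5, 10, 20, 1000)
  expect_equal(st2$velocity_deg_s[1], 0)
  expect_gt(st2$velocity_deg_s[5], 0)
  expect_error(generate_stimulus(0), "positive")
  expect_error(generate_stimulus(-1), "positive")
})

test_that("generate_eye_trace realizes the requested kinematics", {
  st <- generate_stimulus(1, 10, 10, 1000)
  spec <- eye_kinematics_spec(response_gain = 0.5, saccade_rate_hz = 0,
                              fixation_jitter_sd_deg = 0)
  eye <- generate_eye_trace(st, spec, seed = 1)
  vel <- diff(eye$position_deg) * 1000
  expect_equal(max(abs(vel)), 5, tolerance = 0.01)
  # antiphase to the stimulus: velocities anticorrelate
  expect_lt(cor(vel, st$velocity_deg_s[-1]), -0.999)
  # zero gain leaves only saccades and jitter
  spec0 <- eye_kinematics_spec(response_gain = 0, saccade_rate_hz = 0,
                               fixation_jitter_sd_deg = 0.1)
  eye0 <- generate_eye_trace(st, spec0, seed = 2)
  expect_lt(sd(eye0$position_deg), 0.12)
  expect_identical(generate_eye_trace(st, spec0, seed = 2), eye0)
})

test_that("saccade counts follow the Poisson rate", {
  st <- generate_stimulus(1, 10, 60, 500)
  # gain and jitter off: the trace moves only during saccades
  spec <- eye_kinematics_spec(response_gain = 0, saccade_rate_hz = 0.2,
                              fixation_jitter_sd_deg = 0,
                              sample_rate_hz = 500)
  counts <- vapply(1:20, function(s) {
    eye <- generate_eye_trace(st, spec, seed = s)
    moving <- abs(diff(eye$position_deg)) > 1e-9
    sum(diff(moving) == 1) + moving[1]  # distinct movement episodes
  }, numeric(1))
  lambda <- 0.2 * 60
  # episodes undercount only when two saccades collide (rare at this rate)
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 20) + 1)
  eye1 <- generate_eye_trace(st, spec, seed = 3)
  expect_identical(generate_eye_trace(st, spec, seed = 3), eye1)
})

test_that("project_to_cameras realizes the dual-angle forward model", {
  t <- (0:299) / 100
  rig <- camera_rig()
  px <- rig$pixel_scale_mm_per_px
  eye0 <- eye_trace(t, rep(0, 300))
  fr <- project_to_cameras(eye0, rig, r_p_mm = 1)
  d1 <- fr$delta_mm[fr$cam == 1][1]; d2 <- fr$delta_mm[fr$cam == 2][1]
  expect_equal(d1, sin(20 * pi / 180), tolerance = 1e-9)
  expect_equal(d2, sin(20 * pi / 180), tolerance = 1e-9)
  # pupil on camera-2 axis at +20 deg
  fr2 <- project_to_cameras(eye_trace(t, rep(20, 300)), rig, r_p_mm = 1)
  expect_equal(fr2$delta_mm[fr2$cam == 2][1], sin(40 * pi / 180), tolerance = 1e-9)
  expect_equal(fr2$delta_mm[fr2$cam == 1][1], 0, tolerance = 1e-9)
  fr3 <- project_to_cameras(eye_trace(t, rep(10, 300)), rig, r_p_mm = 1.5)
  expect_equal(fr3$delta_mm[fr3$cam == 1][1], 1.5 * sin(10 * pi / 180),
               tolerance = 1e-9)
  expect_equal(fr3$delta_mm[fr3$cam == 2][1], 1.5 * sin(30 * pi / 180),
               tolerance = 1e-9)
  # out-of-range frames are flagged, not clipped
  fr4 <- project_to_cameras(eye_trace(t, rep(85, 300)), rig)
  expect_true(all(!fr4$valid))
})

test_that("camera projection and angle recovery eliminate Rp", {
  t <- (0:299) / 100
  eye <- eye_trace(t, 15 * sin(2 * pi * t / 3))
  rig <- camera_rig()
  for (rp in c(0.8, 1.25, 1.7)) {
    fr <- project_to_cameras(eye, rig, r_p_mm = rp)
    rec <- eye_position_from_frames(fr, rig)
    tru <- approx(eye$time_s, eye$position_deg, xout = rec$time_s)$y
    expect_lt(max(abs(rec$position_deg - tru)), 1e-9)
  }
})

test_that("rendered frames place pupil and CR where requested", {
  fr <- sweep_frames(0)
  spec <- eye_image_spec(noise_sd = 0)
  rend <- render_eye_frames(fr, spec)
  img <- rend$cam1[[1]]
  # centroid of the dark pupil region sits at the pupil landmark
  p <- which(img < 0.2, arr.ind = TRUE)
  expect_lt(abs(mean(p[, "col"]) - fr$pupil_x_px[fr$cam == 1]), 1)
  expect_lt(abs(mean(p[, "row"]) - fr$pupil_y_px[fr$cam == 1]), 1)
  # the CR glint at the image center reaches the global maximum
  # (the distractor glint is rendered equally bright elsewhere)
  expect_equal(max(img[89:92, 119:122]), max(img))
  expect_gt(max(img[89:92, 119:122]), 0.9)
  # seeded renders are identical
  spec_n <- eye_image_spec()
  expect_identical(render_eye_frames(fr, spec_n, seed = 3),
                   render_eye_frames(fr, spec_n, seed = 3))
  # a pupil beyond the border is an error
  bad <- sweep_frames(0)
  bad$pupil_x_px[1] <- 230
  expect_error(render_eye_frames(bad, spec), "bounds")
})

test_that("overhead motion generator orders activity levels", {
  sched <- data.frame(duration_s = c(10, 10, 10),
                      displacement_sd_px = c(0, 1.2, 4),
                      label = c("Still", "Middle", "Active"))
  ov <- generate_overhead_motion(sched, frame_rate_hz = 10, seed = 5)
  expect_length(ov$frames, 300)
  mi <- motion_index(ov)
  by_level <- tapply(mi$raw_motion, ov$labels[seq_len(nrow(mi))], mean)
  expect_true(by_level[["Still"]] < by_level[["Middle"]])
  expect_true(by_level[["Middle"]] < by_level[["Active"]])
  expect_identical(generate_overhead_motion(sched, frame_rate_hz = 10, seed = 5)$frames,
                   ov$frames)
  # zero displacement: frame differences sit at the noise floor
  still <- generate_overhead_motion(
    data.frame(duration_s = 5, displacement_sd_px = 0, label = "Still"),
    frame_rate_hz = 10, noise_sd = 0.01, seed = 6)
  mi0 <- motion_index(still)
  expect_lt(max(mi0$raw_motion), 0.02)
})

test_that("generate_session assembles consistent streams and ground truth", {
  s <- clean_session()
  expect_length(s$sensor$time_s, 60 * 1000)
  expect_length(s$sensor$ttl_pulse_times_s, 60)
  amp <- sensitivity_profile(s$geometry, s$sensor_spec)
  expect_equal(s$truth$k_true, 90 / (pi * amp))
  # flashes are embedded in the camera intensity stream at 1 Hz
  onsets <- detect_sync_flash(s$camera_intensity$mean_intensity)
  expect_gte(length(onsets), 58)
  expect_equal(median(diff(s$camera_intensity$time_s[onsets])), 1,
               tolerance = 0.05)
  # a noiseless session's video-derived eye equals the truth
  ve <- video_eye_of(s, "clean_video_eye")
  tru <- approx(s$truth$eye$time_s, s$truth$eye$position_deg,
                xout = ve$time_s)$y
  expect_lt(max(abs(ve$position_deg - tru)), 1e-9)
})
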