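test_that("amr_response follows the sin(2 theta) bridge model", {
  spec <- amr_sensor_spec(peak_amplitude_mV = 1000)
  expect_equal(amr_response(0, spec)[1, ], c(ch1_mV = 0, ch2_mV = -1000))
  expect_equal(amr_response(22.5, spec)[1, ],
               c(ch1_mV = 1000 / sqrt(2), ch2_mV = -1000 / sqrt(2)))
  # 180-degree periodicity: the bridge senses field axis, not polarity
  expect_equal(amr_response(30, spec), amr_response(210, spec))
  th <- seq(-90, 90, by = 7)
  expect_equal(amr_response(th, spec), amr_response(th + 180, spec))
  # channel 2 is channel 1 tuned 45 degrees away
  expect_equal(amr_response(th, spec)[, 2], amr_response(th - 45, spec)[, 1])
  expect_error(amr_response(NaN, spec), "finite")
  expect_error(amr_sensor_spec(channel_phase_deg = c(0, 30)), "45")
  expect_error(amr_sensor_spec(peak_amplitude_mV = -1), "positive")
})

test_that("baseline offsets shift channels additively", {
  spec <- amr_sensor_spec(peak_amplitude_mV = 500,
                          baseline_offset_mV = c(10, -20))
  v <- amr_response(c(0, 45), spec)
  expect_equal(unname(v[1, ]), c(10, -520))
  expect_equal(unname(v[2, ]), c(510, -20))
})

test_that("sensitivity_profile reproduces the bench anchors and is monotone", {
  spec <- amr_sensor_spec()
  # reference geometry returns the spec amplitude unchanged
  expect_equal(sensitivity_profile(magnet_geometry(0, 0), spec),
               spec$peak_amplitude_mV)
  # anchored so the mean zero-crossing slope matches the bench values
  for (anchor in list(c(0, 224.7), c(3, 127.0), c(5, 28.1))) {
    amp <- sensitivity_profile(magnet_geometry(anchor[1]), spec)
    expect_equal(amp * sqrt(2) / 45, anchor[2], tolerance = 1e-6)
  }
  # monotone non-increasing in vertical distance and horizontal offset
  dv <- seq(0, 7, by = 0.25)
  amps_v <- vapply(dv, function(d)
    sensitivity_profile(magnet_geometry(d), spec), numeric(1))
  expect_true(all(diff(amps_v) <= 1e-9))
  dh <- seq(0, 4, by = 0.25)
  amps_h <- vapply(dh, function(d)
    sensitivity_profile(magnet_geometry(3, d), spec), numeric(1))
  expect_true(all(diff(amps_h) < 0))
  expect_error(magnet_geometry(-1), "non-negative")
})

test_that("estimate_sensitivity matches the closed form A*sqrt(2)/45", {
  th <- seq(-45, 45, by = 0.1)
  for (A in c(1000, 4041.7)) {
    s <- estimate_sensitivity(th, A * sin(2 * th * pi / 180))
    expect_equal(s, A * sqrt(2) / 45, tolerance = 0.005)
  }
  # constant slope is recovered exactly; no crossing is not estimable
  th2 <- seq(-30, 30, by = 0.5)
  expect_equal(estimate_sensitivity(th2, 50 * th2), 50, tolerance = 1e-9)
  expect_true(is.na(estimate_sensitivity(th2, rep(7, length(th2)))))
  # windowed least-squares slope handles noisy sweeps
  v <- 1000 * sin(2 * th * pi / 180) +
    withr::with_seed(4, rnorm(length(th), sd = 5))
  s_w <- estimate_sensitivity(th, v, slope_window_deg = 1)
  expect_equal(s_w, 1000 * sqrt(2) / 45, tolerance = 0.02)
})

test_that("estimate_sensitivity averages across channels and crossings", {
  th <- seq(-90, 90, by = 0.1)
  spec <- amr_sensor_spec(peak_amplitude_mV = 2000)
  s <- estimate_sensitivity(th, amr_response(th, spec))
  expect_length(s, 2)
  expect_equal(s, rep(2000 * sqrt(2) / 45, 2), tolerance = 0.005)
})

test_that("dipole field angle reproduces the on-axis geometry", {
  g <- magnet_geometry(vertical_distance_mm = 3)
  # on-axis dipole field is antiparallel to the in-plane moment
  expect_equal(dipole_field_angle(g, 0), 180)
  th <- seq(-40, 40, by = 5)
  expect_equal((dipole_field_angle(g, th) - th) %% 360, rep(180, length(th)))
  expect_error(dipole_field_angle(magnet_geometry(0, 0), 0), "coincides")
})

test_that("horizontal offset attenuates but does not destroy the dipole response", {
  g <- magnet_geometry(vertical_distance_mm = 3, horizontal_offset_mm = 1.5)
  th <- seq(-22.5, 22.5, by = 0.1)
  phi <- dipole_field_angle(g, th, lever_arm_mm = 1.5)
  phi <- (phi - phi[which.min(abs(th))]) %% 360
  phi <- ifelse(phi > 180, phi - 360, phi)
  mean_slope <- mean(abs(diff(phi) / diff(th)))
  expect_gt(mean_slope, 0.5)
  expect_lt(mean_slope, 1)
})

test_that("dipole-variant sensitivity is monotone in offset and tilt-invariant", {
  s0 <- dipole_sweep_sensitivity(magnet_geometry(3, 0))
  s1 <- dipole_sweep_sensitivity(magnet_geometry(3, 1), lever_arm_mm = 1)
  s2 <- dipole_sweep_sensitivity(magnet_geometry(3, 2), lever_arm_mm = 1)
  expect_true(all(s1[1] < s0[1], s2[1] < s1[1]))
  # a 45-degree tilt of the aligned magnet leaves sensitivity unchanged:
  # the saturated AMR bridge senses field direction, and on-axis the
  # in-plane field angle tracks the magnet angle regardless of tilt
  st <- dipole_sweep_sensitivity(magnet_geometry(3, 0, tilt_deg = 45))
  expect_lt(abs(st[1] / s0[1] - 1), 0.05)
})

test_that("simulate_sensor_trace composes response, noise and TTL train", {
  t <- (0:999) / 1000
  eye_const <- eye_trace(t, rep(3, 1000))
  spec0 <- amr_sensor_spec(noise_sd_mV = 0)
  tr <- simulate_sensor_trace(eye_const, spec0)
  expect_equal(diff(range(tr$v_mV[, 1])), 0)
  expect_equal(diff(range(tr$v_mV[, 2])), 0)
  # small-angle linearity of channel 1
  eye_sin <- eye_trace(t, 10 * sin(2 * pi * t))
  tr2 <- simulate_sensor_trace(eye_sin, spec0, magnet_geometry(3))
  r2 <- summary(lm(tr2$v_mV[, 1] ~ eye_sin$position_deg))$r.squared
  expect_gt(r2, 0.999)
  # seeded determinism, bit for bit
  spec_n <- amr_sensor_spec(noise_sd_mV = 5)
  a <- simulate_sensor_trace(eye_sin, spec_n, seed = 9)
  b <- simulate_sensor_trace(eye_sin, spec_n, seed = 9)
  expect_identical(a, b)
  # 1 Hz TTL pulse train spans the trace
  expect_equal(tr$ttl_pulse_times_s, 0)
  eye10 <- eye_trace((0:9999) / 1000, rep(0, 10000))
  expect_length(simulate_sensor_trace(eye10, spec0)$ttl_pulse_times_s, 10)
})
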