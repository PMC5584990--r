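test_that("one-channel position fit is exact on constructed data", {
  d <- make_aligned()
  fit <- fit_position_one_channel(d$e, d$m)
  expect_equal(fit$best_channel, 1)
  expect_equal(fit$coefficients$k1_1, 0.005, tolerance = 1e-9)
  expect_equal(fit$coefficients$k2_1, 1, tolerance = 1e-9)
  expect_equal(abs(fit$r_per_channel[1]), 1, tolerance = 1e-9)
  expect_equal(fit$k, 0.005, tolerance = 1e-9)
  # uncorrelated noise: low-quality fit flagged by r near zero
  d2 <- withr::with_seed(3, list(e = rnorm(2000), m = cbind(rnorm(2000), rnorm(2000))))
  fit2 <- fit_position_one_channel(d2$e, d2$m)
  expect_lt(max(abs(fit2$r_per_channel)), 0.1)
  # inverted polarity is selected by |r|
  fit3 <- fit_position_one_channel(-d$e, d$m)
  expect_equal(fit3$best_channel, 1)
  expect_lt(fit3$r_per_channel[1], -0.99)
  # constant channel is unusable, not fatal
  d$m[, 2] <- 5
  fit4 <- fit_position_one_channel(d$e, d$m)
  expect_true(is.na(fit4$coefficients$k1_2))
  expect_equal(fit4$best_channel, 1)
})

test_that("two-channel ridge reaches the OLS limit and handles collinearity", {
  d <- withr::with_seed(22, {
    m1 <- 50 * sin(2 * pi * (1:3000) / 700)
    m2 <- rnorm(3000, sd = 5)
    list(e = 2 * m1 + 3, m = cbind(m1, m2))
  })
  fit <- fit_position_two_channel(d$e, d$m)
  expect_equal(fit$coefficients$k1, 2, tolerance = 0.01)
  expect_equal(fit$coefficients$k3, 3, tolerance = 0.01 * 3)
  expect_gt(fit$variance_explained, 0.9999)
  # perfectly collinear channels: coefficients shrink but prediction holds
  dc <- withr::with_seed(23, {
    m1 <- 50 * sin(2 * pi * (1:3000) / 700)
    list(e = 0.01 * m1, m = cbind(m1, m1 + rnorm(3000, sd = 0.5)))
  })
  fitc <- fit_position_two_channel(dc$e, dc$m)
  one <- fit_position_one_channel(dc$e, dc$m)
  expect_true(is.finite(fitc$variance_explained))
  expect_equal(fitc$variance_explained, one$variance_explained,
               tolerance = 0.01)
  expect_error(fit_position_two_channel(d$e, d$m, lambda_grid = numeric(0)),
               "empty")
})

test_that("quadratic model captures an injected nonlinearity", {
  d <- withr::with_seed(24, {
    m1 <- seq(-300, 300, length.out = 3000)
    m2 <- rnorm(3000, sd = 10)
    list(e = 0.001 * m1^2, m = cbind(m1, m2))
  })
  fq <- fit_position_quadratic(d$e, d$m)
  fl <- fit_position_two_channel(d$e, d$m)
  expect_gt(fq$variance_explained, 0.999)
  expect_lt(fl$variance_explained, 0.9)
  expect_equal(fq$coefficients$k3, 0.001, tolerance = 0.01)
  # on linear ground truth the quadratic terms vanish
  dl <- make_aligned()
  fq2 <- fit_position_quadratic(dl$e, dl$m)
  expect_lt(abs(fq2$coefficients$k3) * max(dl$m[, 1]^2),
            0.01 * diff(range(dl$e)))
  expect_equal(fq2$variance_explained,
               fit_position_two_channel(dl$e, dl$m)$variance_explained,
               tolerance = 1e-4)
})

test_that("training variance explained respects the model hierarchy", {
  s <- noisy_session()
  ve <- video_eye_of(s, "noisy_video_eye")
  onsets <- detect_sync_flash(s$camera_intensity$mean_intensity)
  al <- align_streams(ve, s$camera_intensity$time_s[onsets], s$sensor)
  tiny <- 1e-8
  f1 <- fit_position_one_channel(al)
  f2 <- fit_position_two_channel(al, lambda_grid = tiny)
  f3 <- fit_position_quadratic(al, lambda_grid = tiny)
  expect_gte(f2$variance_explained, f1$variance_explained - 1e-9)
  expect_gte(f3$variance_explained, f2$variance_explained - 1e-9)
})

test_that("velocity calibration recovers the amplitude ratio", {
  t <- (0:59999) / 1000
  e <- 10 * sin(2 * pi * t)
  eye <- eye_trace(t, e)
  sens <- sensor_trace(t, cbind(200 * e, rnorm(60000, sd = 3)))
  vc <- fit_velocity_calibration(eye, sens, 1)
  expect_equal(vc$chosen_channel, 1)
  expect_equal(vc$factor, 0.005, tolerance = 1e-3)
  expect_equal(vc$a_vid, 2 * pi * 10 * sin(pi * 0.05) / (pi * 0.05),
               tolerance = 0.01)
  expect_true(vc$ok)
  # a pure time shift between the streams changes nothing
  e_shift <- 10 * sin(2 * pi * (t - 0.2))
  vc2 <- fit_velocity_calibration(eye_trace(t, e_shift), sens, 1)
  expect_equal(vc2$factor, vc$factor, tolerance = 1e-3)
  # uninformative channels: calibration failure status
  bad <- sensor_trace(t, withr::with_seed(5, cbind(rnorm(60000), rnorm(60000))))
  expect_false(fit_velocity_calibration(eye, bad, 1)$ok)
})

test_that("position and velocity methods agree on a real session", {
  s <- noisy_session()
  ve <- video_eye_of(s, "noisy_video_eye")
  onsets <- detect_sync_flash(s$camera_intensity$mean_intensity)
  ev <- differentiate(ve)
  vmask <- detect_artifacts(ev, 50, source = "video")
  mv <- differentiate(s$sensor)
  smask <- mask_union(detect_artifacts(mv$ch1, 5, source = "sensor"),
                      detect_artifacts(mv$ch2, 5, source = "sensor"))
  al <- align_streams(ve, s$camera_intensity$time_s[onsets], s$sensor,
                      video_mask = vmask, sensor_mask = smask)
  pos <- fit_position_one_channel(al)
  vel <- fit_velocity_calibration(ve, s$sensor, 1)
  expect_lt(abs(pos$k / s$truth$k_true - 1), 0.05)
  expect_lt(abs(vel$factor / s$truth$k_true - 1), 0.05)
  expect_lt(abs(vel$factor / pos$k - 1), 0.02)
})

test_that("apply_calibration inverts the constructed maps", {
  t <- (0:999) / 1000
  e <- 3 * sin(2 * pi * t)
  m1 <- (e - 1) / 0.005
  sens <- sensor_trace(t, cbind(m1, rep(0, 1000)))
  calib <- structure(
    list(model = "one_channel",
         coefficients = list(k1_1 = 0.005, k2_1 = 1, k1_2 = NA, k2_2 = NA),
         best_channel = 1),
    class = "position_calibration")
  rec <- apply_calibration(sens, calib)
  expect_equal(rec$position_deg, e, tolerance = 1e-12)
  # zero voltage maps to the offset
  sens0 <- sensor_trace(t, matrix(0, 1000, 2))
  expect_equal(apply_calibration(sens0, calib)$position_deg,
               rep(1, 1000))
  # end-to-end: simulate at small angles, calibrate, recover
  eye <- eye_trace(t, 1.5 * sin(2 * pi * t))
  sim <- simulate_sensor_trace(eye, amr_sensor_spec(noise_sd_mV = 0),
                               magnet_geometry(3))
  fit <- fit_position_one_channel(eye$position_deg, sim$v_mV)
  rec2 <- apply_calibration(sim, fit)
  expect_gt(cor(rec2$position_deg, eye$position_deg)^2, 0.999)
})

test_that("calibration drift follows the day-1-relative percent change", {
  expect_equal(calibration_drift(c(0.010, 0.012))$delta_pct_series,
               c(0, 20), tolerance = 1e-9)
  expect_equal(calibration_drift(rep(0.01, 5))$delta_pct_series, rep(0, 5))
  expect_equal(calibration_drift(c(0.010, 0.008, 0.011))$delta_pct_series,
               c(0, 20, 10), tolerance = 1e-9)
  expect_error(calibration_drift(c(0, 1)), "non-zero")
})

test_that("blocked ridge cross-validation is deterministic", {
  d <- withr::with_seed(26, {
    m1 <- 100 * sin(2 * pi * (1:3000) / 600)
    m2 <- m1 * 0.5 + rnorm(3000, sd = 20)
    list(e = 0.004 * m1 + 0.001 * m2 + rnorm(3000, sd = 0.05),
         m = cbind(m1, m2))
  })
  f1 <- fit_position_two_channel(d$e, d$m, seed = 1)
  f2 <- fit_position_two_channel(d$e, d$m, seed = 99)
  expect_identical(f1$ridge_lambda, f2$ridge_lambda)
  expect_identical(f1$coefficients, f2$coefficients)
})
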