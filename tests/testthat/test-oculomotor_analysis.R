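test_that("fit_sine is exact on its basis and robust to gaps", {
  t <- (0:9999) / 1000
  y <- 3 * sin(2 * pi * t + 30 * pi / 180) + 7
  f <- fit_sine(t, y, 1)
  expect_equal(f$amplitude, 3, tolerance = 1e-9)
  expect_equal(f$phase_deg, 30, tolerance = 1e-9)
  expect_equal(f$offset, 7, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  # white noise: negligible amplitude, r2 near zero
  fn <- withr::with_seed(2, fit_sine(t, rnorm(10000), 1))
  expect_lt(fn$amplitude, 0.1)
  expect_lt(fn$r2, 0.01)
  # 40% of samples masked: amplitude within 1% of the full fit
  drop <- withr::with_seed(3, sample(10000, 4000))
  fg <- fit_sine(t[-drop], (y + withr::with_seed(4, rnorm(10000, sd = 0.3)))[-drop], 1)
  expect_equal(fg$amplitude, 3, tolerance = 0.01)
  expect_error(fit_sine((0:99) / 100, rnorm(100), 1), "2 stimulus cycles")
})

test_that("gain_phase is zero-phase for a compensatory response", {
  st <- generate_stimulus(1, 10, 10, 1000)
  vel_comp <- velocity_trace(st$time_s, -0.5 * st$velocity_deg_s, "deg/s")
  gp <- gain_phase(vel_comp, st)
  expect_equal(gp$gain, 0.5, tolerance = 1e-6)
  expect_equal(gp$phase_deg, 0, tolerance = 1e-6)
  # following the stimulus instead of opposing it is 180 degrees off
  vel_follow <- velocity_trace(st$time_s, 0.5 * st$velocity_deg_s, "deg/s")
  expect_equal(abs(gain_phase(vel_follow, st)$phase_deg), 180, tolerance = 1e-6)
})

test_that("gain and phase are recovered across the frequency battery", {
  for (f in c(0.2, 0.5, 1, 2, 5)) {
    st <- generate_stimulus(f, 10, max(20, 4 / f), 1000)
    eye <- generate_eye_trace(st, eye_kinematics_spec(
      response_gain = 0.7, response_phase_deg = 10,
      saccade_rate_hz = 0, fixation_jitter_sd_deg = 0), seed = 1)
    gp <- gain_phase(differentiate(eye), st)
    expect_lt(abs(gp$gain - 0.7), 0.02)
    expect_lt(abs(gp$phase_deg - 10), 2)
  }
})

test_that("gain_phase recovers kinematics through a noisy session", {
  s <- generate_session(seed = 41, frequency_hz = 2,
                        kinematics = eye_kinematics_spec(
                          response_gain = 0.7, response_phase_deg = 10))
  ev <- differentiate(s$truth$eye)
  m <- detect_artifacts(ev, 50)
  gp <- gain_phase(ev, s$stimulus, mask = m)
  expect_lt(abs(gp$gain - 0.7), 0.02)
  expect_lt(abs(gp$phase_deg - 10), 2)
})

test_that("spatial_resolution is unbiased on white fixation jitter", {
  for (sdv in c(0.05, 0.10, 0.5)) {
    tr <- withr::with_seed(5, eye_trace((0:9999) / 1000,
                                        rnorm(10000, sd = sdv)))
    sr <- spatial_resolution(tr)
    expect_lt(abs(sr$resolution_deg / sdv - 1), 0.10)
    expect_length(sr$epoch_sds_deg, 3)
  }
  # constant trace: exactly zero
  tr0 <- eye_trace((0:9999) / 1000, rep(2, 10000))
  expect_equal(spatial_resolution(tr0)$resolution_deg, 0)
  # uniform drift fails the stationarity criterion everywhere
  trd <- eye_trace((0:9999) / 1000, (0:9999) / 1000)
  expect_error(spatial_resolution(trd), "0 stationary epochs")
})

test_that("motion index labels the synthetic activity schedule", {
  sched <- data.frame(duration_s = c(40, 40, 40),
                      displacement_sd_px = c(0, 1.2, 4),
                      label = c("Still", "Middle", "Active"))
  ov <- generate_overhead_motion(sched, seed = 3)
  mi <- motion_index(ov)
  n <- nrow(mi)
  # tertile counts within 1 of n/3
  counts <- table(mi$label)
  expect_lte(abs(counts[["Active"]] - n / 3), 1)
  expect_lte(abs(counts[["Still"]] - n / 3), 1)
  # >= 95% agreement with ground truth away from transitions
  truth <- ov$labels[seq_len(n)]
  trans <- cumsum(sched$duration_s)[1:2]
  away <- !vapply(mi$time_s, function(x) any(abs(x - trans) <= 2), logical(1))
  use <- away & truth != "Middle"
  expect_gte(mean(mi$label[use] == truth[use]), 0.95)
  expect_error(motion_index(ov$frames[1], frame_rate_hz = 15), "2 frames")
})

test_that("motion index is invariant to global brightness offsets", {
  sched <- data.frame(duration_s = c(10, 10), displacement_sd_px = c(0, 3),
                      label = c("Still", "Active"))
  ov <- generate_overhead_motion(sched, frame_rate_hz = 10, seed = 9)
  mi <- motion_index(ov)
  shifted <- lapply(ov$frames, function(f) f + 0.17)
  mi2 <- motion_index(shifted, frame_rate_hz = 10)
  expect_equal(mi2$raw_motion, mi$raw_motion, tolerance = 1e-12)
  expect_identical(mi2$label, mi$label)
})

test_that("binocular statistics follow the stated conventions", {
  t <- (0:999) / 1000
  right <- eye_trace(t, rep(3, 1000))
  left <- eye_trace(t, rep(-2, 1000))
  b <- binocular_stats(left, right)
  expect_equal(b$divergence_mean_deg, 5)
  expect_equal(b$divergence_sd_deg, 0)
  # conjugate eyes: constant zero divergence
  conj <- eye_trace(t, 2 * sin(2 * pi * t))
  b2 <- binocular_stats(conj, conj)
  expect_equal(b2$divergence_mean_deg, 0)
  expect_equal(b2$divergence_sd_deg, 0)
  # independent jitter: divergence SD adds in quadrature
  base <- 2 * sin(2 * pi * (0:59999) / 1000)
  tl <- (0:59999) / 1000
  l <- eye_trace(tl, base + withr::with_seed(6, rnorm(60000, sd = 0.1)))
  r <- eye_trace(tl, base + withr::with_seed(7, rnorm(60000, sd = 0.1)))
  b3 <- binocular_stats(l, r)
  expect_equal(b3$divergence_sd_deg, 0.1 * sqrt(2), tolerance = 0.02)
  # per-condition breakdown when labels are supplied
  lbl <- rep(c("Still", "Active"), each = 30000)
  b4 <- binocular_stats(l, r, labels = lbl)
  expect_setequal(b4$condition, c("all", "Active", "Still"))
  expect_error(binocular_stats(l, eye_trace(tl + 1, base)), "aligned")
})

test_that("eye-head velocity relation recovers constructed slopes", {
  h <- withr::with_seed(8, rnorm(5000, sd = 20))
  expect_equal(eye_head_relation(-0.5 * h, h)$slope, -0.5, tolerance = 1e-9)
  expect_equal(eye_head_relation(-0.5 * h, h)$r, -1, tolerance = 1e-9)
  ind <- withr::with_seed(9, rnorm(5000))
  expect_lt(abs(eye_head_relation(ind, h)$r), 0.05)
  noisy <- -0.6 * h + withr::with_seed(10, rnorm(5000, sd = 1.2))
  rel <- eye_head_relation(noisy, h)
  expect_equal(rel$slope, -0.6, tolerance = 0.02)
  expect_lt(rel$r, -0.9)
  expect_error(eye_head_relation(h, rep(1, 5000)), "constant")
})
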