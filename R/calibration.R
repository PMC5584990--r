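# Calibration of sensor voltages into eye angle. Position methods regress
# video-derived eye position on the sensor channels: one channel at a time
# (e = k1 m + k2), both channels with ridge regularization
# (e = k1 m1 + k2 m2 + k3), or with added quadratic terms
# (e = k1 m1 + k2 m2 + k3 m1^2 + k4 m2^2 + k5). The velocity method takes
# the ratio of sine amplitudes fitted to the differentiated video and sensor
# traces (e_dot = (A_vid / A_mag) m_dot) and needs no temporal alignment.

.DEFAULT_LAMBDA_GRID <- 10^seq(-6, 3, length.out = 25)

.included <- function(eye_deg, v_mV, mask) {
  v_mV <- as.matrix(v_mV)
  if (nrow(v_mV) != length(eye_deg)) {
    stop("eye and sensor traces must be aligned to equal length", call. = FALSE)
  }
  keep <- is.finite(eye_deg) & apply(is.finite(v_mV), 1, all)
  if (!is.null(mask)) keep <- keep & !as.logical(mask)
  if (sum(keep) <= 100L) {
    stop("more than 100 included samples are required for calibration",
         call. = FALSE)
  }
  list(e = eye_deg[keep], m = v_mV[keep, , drop = FALSE], keep = keep)
}

.as_aligned_args <- function(eye_deg, v_mV, mask) {
  if (inherits(eye_deg, "aligned_streams")) {
    al <- eye_deg
    list(eye = al$eye_deg_video, v = al$v_mV, mask = al$excluded)
  } else list(eye = eye_deg, v = v_mV, mask = mask)
}

#' Single-channel position calibration
#'
#' Ordinary least squares of video-derived eye position on each sensor
#' channel separately: `e_c(t) = k1_c m_c(t) + k2_c`. The channel more
#' strongly correlated (by |r|; implant polarity may invert the sign) with
#' the video eye position is selected; its slope `k1` is the calibration
#' factor (deg/mV).
#'
#' @param eye_deg Aligned video-derived eye position (deg) on the sensor
#'   grid, or an `aligned_streams` object (then `v_mV`/`mask` are taken from
#'   it).
#' @param v_mV Two-column sensor voltage matrix (mV).
#' @param mask Optional exclusion mask (TRUE = excluded).
#' @return A `position_calibration` with model `"one_channel"`:
#'   `coefficients` (k1, k2 per channel), `best_channel`, `r_per_channel`,
#'   `k` (best-channel calibration factor), `variance_explained`.
#' @export
fit_position_one_channel <- function(eye_deg, v_mV = NULL, mask = NULL) {
  a <- .as_aligned_args(eye_deg, v_mV, mask)
  d <- .included(a$eye, a$v, a$mask)
  fits <- lapply(1:2, function(c) {
    m <- d$m[, c]
    if (stats::sd(m) == 0) return(NULL)  # constant channel: unusable
    f <- stats::lm(d$e ~ m)
    list(k1 = unname(stats::coef(f)[2]), k2 = unname(stats::coef(f)[1]),
         r = stats::cor(d$e, m),
         ve = stats::cor(d$e, m)^2)
  })
  r <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$r, numeric(1))
  if (all(is.na(r))) stop("both channels are degenerate", call. = FALSE)
  best <- which.max(abs(r))
  structure(
    list(model = "one_channel",
         coefficients = list(
           k1_1 = if (is.null(fits[[1]])) NA_real_ else fits[[1]]$k1,
           k2_1 = if (is.null(fits[[1]])) NA_real_ else fits[[1]]$k2,
           k1_2 = if (is.null(fits[[2]])) NA_real_ else fits[[2]]$k1,
           k2_2 = if (is.null(fits[[2]])) NA_real_ else fits[[2]]$k2),
         best_channel = best, r_per_channel = r,
         k = fits[[best]]$k1,
         variance_explained = fits[[best]]$ve,
         n_included = length(d$e)),
    class = "position_calibration"
  )
}

# Ridge solve on standardized regressors; returns coefficients on the
# original scale plus the intercept.
.ridge_fit <- function(X, y, lambda) {
  mu <- colMeans(X); sx <- apply(X, 2, stats::sd)
  sx[sx == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sx, "/")
  yc <- y - mean(y)
  p <- ncol(Xs)
  b_std <- solve(crossprod(Xs) + diag(lambda, p), crossprod(Xs, yc))
  b <- as.numeric(b_std) / sx
  list(beta = b, intercept = mean(y) - sum(b * mu))
}

.ridge_cv <- function(X, y, lambda_grid, n_folds, seed) {
  n <- nrow(X)
  if (length(lambda_grid) == 0L) stop("empty lambda grid", call. = FALSE)
  # contiguous time blocks: interleaved folds leak autocorrelated samples
  fold <- ceiling(seq_len(n) / n * n_folds)
  cv_err <- vapply(lambda_grid, function(lam) {
    errs <- vapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      if (sum(tr) < ncol(X) + 1L || sum(!tr) == 0L) return(NA_real_)
      fit <- .ridge_fit(X[tr, , drop = FALSE], y[tr], lam)
      pred <- X[!tr, , drop = FALSE] %*% fit$beta + fit$intercept
      mean((y[!tr] - pred)^2)
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  lambda_grid[which.min(cv_err)]
}

.fit_position_ridge <- function(eye_deg, v_mV, mask, lambda_grid, n_folds,
                                seed, quadratic) {
  a <- .as_aligned_args(eye_deg, v_mV, mask)
  d <- .included(a$eye, a$v, a$mask)
  X <- if (quadratic) {
    cbind(d$m[, 1], d$m[, 2], d$m[, 1]^2, d$m[, 2]^2)
  } else {
    cbind(d$m[, 1], d$m[, 2])
  }
  lam <- .ridge_cv(X, d$e, lambda_grid, n_folds, seed)
  fit <- .ridge_fit(X, d$e, lam)  # final fit on all calibration data
  pred <- as.numeric(X %*% fit$beta + fit$intercept)
  ve <- 1 - sum((d$e - pred)^2) / sum((d$e - mean(d$e))^2)
  co <- if (quadratic) {
    list(k1 = fit$beta[1], k2 = fit$beta[2], k3 = fit$beta[3],
         k4 = fit$beta[4], k5 = fit$intercept)
  } else {
    list(k1 = fit$beta[1], k2 = fit$beta[2], k3 = fit$intercept)
  }
  structure(
    list(model = if (quadratic) "quadratic" else "two_channel",
         coefficients = co, ridge_lambda = lam,
         lambda_grid = lambda_grid, n_folds = n_folds,
         variance_explained = ve, n_included = length(d$e)),
    class = "position_calibration"
  )
}

#' Two-channel ridge position calibration
#'
#' Fits `e(t) = k1 m1(t) + k2 m2(t) + k3` by ridge regression (the two
#' channels are strongly correlated, so L2 regularization guards against
#' overfitting). The penalty is selected by 10-fold cross-validation over a
#' log-spaced grid, with folds formed as contiguous time blocks; the
#' regression is then re-run on all calibration data at the selected
#' penalty. Regressors are standardized for the penalty and coefficients
#' returned on the original scale.
#'
#' @inheritParams fit_position_one_channel
#' @param lambda_grid Ridge penalty grid. Default 25 points, log-spaced over
#'   \[1e-6, 1e3\].
#' @param n_folds Number of contiguous cross-validation blocks. Default 10.
#' @param seed Unused by the deterministic blocked folds; kept so callers
#'   can thread a seed uniformly.
#' @return A `position_calibration` with model `"two_channel"`.
#' @export
fit_position_two_channel <- function(eye_deg, v_mV = NULL, mask = NULL,
                                     lambda_grid = .DEFAULT_LAMBDA_GRID,
                                     n_folds = 10, seed = NULL) {
  .fit_position_ridge(eye_deg, v_mV, mask, lambda_grid, n_folds, seed,
                      quadratic = FALSE)
}

#' Quadratic position calibration
#'
#' As [fit_position_two_channel()] with regressors `m1, m2, m1^2, m2^2`:
#' `e(t) = k1 m1 + k2 m2 + k3 m1^2 + k4 m2^2 + k5`, to capture eye positions
#' falling in a non-linear portion of the sensor output.
#'
#' @inheritParams fit_position_two_channel
#' @return A `position_calibration` with model `"quadratic"`.
#' @export
fit_position_quadratic <- function(eye_deg, v_mV = NULL, mask = NULL,
                                   lambda_grid = .DEFAULT_LAMBDA_GRID,
                                   n_folds = 10, seed = NULL) {
  .fit_position_ridge(eye_deg, v_mV, mask, lambda_grid, n_folds, seed,
                      quadratic = TRUE)
}

#' Velocity-based calibration by sine-amplitude ratio
#'
#' Upsamples the video eye trace to the sensor sampling rate (linear
#' interpolation), differentiates it and each raw sensor channel with the
#' 50 ms sliding window, desaccades both with the standard velocity
#' thresholds, and fits each velocity trace with a sine at the stimulus
#' frequency. Differentiating after upsampling lets the 50 ms window
#' average over the interpolated frame noise, and puts both streams through
#' the identical differentiator so its frequency response cancels in the
#' amplitude ratio. The channel with the higher r-squared is selected
#' and the calibration factor is the amplitude ratio
#' `A_vid / A_mag` (deg/mV). Because only amplitudes enter, the method does
#' not require temporal alignment of the two recordings.
#'
#' @param video_eye An [eye_trace()] from video-oculography (native rate).
#' @param sensor A [sensor_trace()].
#' @param stimulus_frequency_hz Known stimulus frequency (Hz).
#' @param video_threshold_deg_s,magnet_threshold_mV_ms Desaccading
#'   thresholds. Defaults 50 deg/s and 5 mV/ms.
#' @param window_ms Differentiation window (ms). Default 50.
#' @param r2_floor Minimum acceptable sine-fit r-squared on the chosen
#'   channel; below it the calibration is flagged failed. Default 0.5.
#' @return A `velocity_calibration`: `a_vid` (deg/s), `a_mag` (mV/s),
#'   `factor` (deg/mV), `chosen_channel`, `r2_per_channel`, `ok`.
#' @export
fit_velocity_calibration <- function(video_eye, sensor,
                                     stimulus_frequency_hz,
                                     video_threshold_deg_s = 50,
                                     magnet_threshold_mV_ms = 5,
                                     window_ms = 50, r2_floor = 0.5) {
  if (video_eye$sample_rate_hz < sensor$sample_rate_hz) {
    # upsample video onto the sensor rate before differentiating; no
    # temporal registration of the two clocks is needed for amplitudes
    n <- round((video_eye$time_s[length(video_eye$time_s)] -
                  video_eye$time_s[1]) * sensor$sample_rate_hz)
    tt <- video_eye$time_s[1] + (seq_len(n) - 1) / sensor$sample_rate_hz
    video_eye <- eye_trace(
      tt, stats::approx(video_eye$time_s, video_eye$position_deg,
                        xout = tt, rule = 2)$y,
      sensor$sample_rate_hz)
  }
  ev <- differentiate(video_eye, window_ms)
  vmask <- detect_artifacts(ev, video_threshold_deg_s, source = "video")
  ef <- fit_sine(ev$time_s[!vmask], ev$value[!vmask], stimulus_frequency_hz)

  mv <- differentiate(sensor, window_ms)
  ch <- lapply(1:2, function(c) {
    m <- detect_artifacts(mv[[c]], magnet_threshold_mV_ms, source = "sensor")
    # amplitudes are taken in mV/s for the ratio with deg/s
    fit_sine(mv[[c]]$time_s[!m], mv[[c]]$value[!m] * 1000,
             stimulus_frequency_hz)
  })
  r2 <- vapply(ch, `[[`, numeric(1), "r2")
  best <- which.max(r2)
  ok <- r2[best] >= r2_floor
  structure(
    list(a_vid = ef$amplitude, a_mag = ch[[best]]$amplitude,
         factor = ef$amplitude / ch[[best]]$amplitude,
         chosen_channel = best, r2_per_channel = r2,
         video_fit_r2 = ef$r2, ok = ok),
    class = "velocity_calibration"
  )
}

#' Apply a calibration to sensor data
#'
#' Maps sensor voltages (position models) or sensor velocity (velocity
#' factor) into eye units. Deterministic affine/quadratic map; the returned
#' trace records which calibration produced it.
#'
#' @param sensor A [sensor_trace()] (position models) or a
#'   [velocity_trace()] in mV/ms (velocity calibration).
#' @param calibration A `position_calibration` or `velocity_calibration`.
#' @param channel Channel for one-channel models; defaults to the fitted
#'   best channel.
#' @return An [eye_trace()] (deg) or a [velocity_trace()] in deg/s.
#' @export
apply_calibration <- function(sensor, calibration, channel = NULL) {
  if (inherits(calibration, "velocity_calibration")) {
    if (!inherits(sensor, "velocity_trace") || sensor$units != "mV/ms") {
      stop("velocity calibration applies to a mV/ms velocity trace", call. = FALSE)
    }
    out <- velocity_trace(sensor$time_s,
                          sensor$value * 1000 * calibration$factor,
                          "deg/s", sensor$window_ms)
    attr(out, "calibration") <- "velocity"
    return(out)
  }
  if (!inherits(sensor, "sensor_trace")) {
    stop("position calibration applies to a sensor_trace", call. = FALSE)
  }
  co <- calibration$coefficients
  e <- switch(calibration$model,
    one_channel = {
      ch <- channel %||% calibration$best_channel
      k1 <- co[[paste0("k1_", ch)]]; k2 <- co[[paste0("k2_", ch)]]
      if (!is.finite(k1)) stop("requested channel was unusable", call. = FALSE)
      k1 * sensor$v_mV[, ch] + k2
    },
    two_channel = co$k1 * sensor$v_mV[, 1] + co$k2 * sensor$v_mV[, 2] + co$k3,
    quadratic = co$k1 * sensor$v_mV[, 1] + co$k2 * sensor$v_mV[, 2] +
      co$k3 * sensor$v_mV[, 1]^2 + co$k4 * sensor$v_mV[, 2]^2 + co$k5,
    stop("unknown calibration model", call. = FALSE)
  )
  out <- eye_trace(sensor$time_s, e, sensor$sample_rate_hz)
  attr(out, "calibration") <- calibration$model
  out
}

#' Day-to-day calibration drift
#'
#' Absolute percent change of the calibration factor relative to day 1:
#' `Dk_n = |k_n - k_1| / k_1 * 100`.
#'
#' @param k_series Calibration factors, day 1 first. `k_series[1]` must be
#'   non-zero.
#' @return A `calibration_drift`: `k_series` and `delta_pct_series`
#'   (with `delta_pct_series[1] == 0`).
#' @export
calibration_drift <- function(k_series) {
  if (k_series[1] == 0) stop("day-1 calibration factor must be non-zero",
                             call. = FALSE)
  structure(
    list(k_series = k_series,
         delta_pct_series = abs(k_series - k_series[1]) / k_series[1] * 100),
    class = "calibration_drift"
  )
}

#' @export
print.position_calibration <- function(x, ...) {
  cat(sprintf("<position_calibration> model %s, variance explained %.4f",
              x$model, x$variance_explained))
  if (x$model == "one_channel") {
    cat(sprintf(", best channel %d, k = %.5g deg/mV", x$best_channel, x$k))
  } else {
    cat(sprintf(", lambda = %.3g", x$ridge_lambda))
  }
  cat(sprintf(", n = %d\n", x$n_included))
  invisible(x)
}

#' @export
print.velocity_calibration <- function(x, ...) {
  cat(sprintf(paste0("<velocity_calibration> factor %.5g deg/mV ",
                     "(A_vid %.4g deg/s / A_mag %.4g mV/s), channel %d, ",
                     "r2 %.4f%s\n"),
              x$factor, x$a_vid, x$a_mag, x$chosen_channel,
              x$r2_per_channel[x$chosen_channel],
              if (x$ok) "" else " [FAILED: r2 below floor]"))
  invisible(x)
}
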