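# Oculomotor metrics: gain and phase of VOR/OKR responses from sinusoidal
# fits to desaccaded eye velocity, spatial resolution from stationary
# epochs, motion indexing of overhead video with Active/Still tertiles,
# binocular divergence, and the eye-head velocity relation.

#' Sinusoid fit at a known frequency
#'
#' Linear least squares on a sin/cos + DC basis at the given frequency
#' (convex and exact for a sinusoid; tolerates irregular or gappy samples,
#' so masked traces can be fitted directly). Amplitude is non-negative with
#' the sign absorbed into the phase: the fit is
#' `A * sin(2 pi f t + phase) + offset`.
#'
#' @param time_s Sample times (s); gaps allowed.
#' @param value Samples, same length.
#' @param frequency_hz Known frequency (Hz). At least 2 cycles of data must
#'   be spanned.
#' @return A list: `amplitude`, `phase_deg` in (-180, 180\], `offset`, `r2`.
#' @export
fit_sine <- function(time_s, value, frequency_hz) {
  ok <- is.finite(time_s) & is.finite(value)
  time_s <- time_s[ok]; value <- value[ok]
  if (diff(range(time_s)) < 2 / frequency_hz) {
    stop("at least 2 stimulus cycles are required for a sine fit", call. = FALSE)
  }
  w <- 2 * pi * frequency_hz
  s <- sin(w * time_s); cc <- cos(w * time_s)
  f <- stats::lm(value ~ s + cc)
  a <- unname(stats::coef(f)["s"]); b <- unname(stats::coef(f)["cc"])
  sst <- sum((value - mean(value))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(f)^2) / sst else 1
  list(amplitude = sqrt(a^2 + b^2),
       phase_deg = .wrap180(atan2(b, a) * 180 / pi),
       offset = unname(stats::coef(f)[1]),
       r2 = r2)
}

# amplitude response of the centered least-squares slope filter at
# frequency f, relative to an ideal differentiator
.slope_window_attenuation <- function(f, fs, window_ms) {
  half <- max(1L, round(window_ms / 1000 * fs / 2))
  j <- 1:half
  w <- 2 * pi * f / fs
  sum(2 * j * sin(w * j)) / (w * sum(2 * j^2))
}

.wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

#' Gain and phase of the eye-velocity response
#'
#' Gain is the amplitude of a sinusoidal fit to the (desaccaded) eye
#' velocity divided by the stimulus amplitude; phase is reported relative to
#' the ideal compensatory response, so 0 means the eye perfectly opposes
#' the stimulus and positive values are phase lead.
#'
#' A sliding-window slope differentiator attenuates a sinusoid by a known
#' frequency-dependent factor; when the velocity trace carries its window
#' width this attenuation is divided out by default, so the reported gain
#' is unbiased at every stimulus frequency.
#'
#' @param eye_velocity A [velocity_trace()] in deg/s (desaccaded: excluded
#'   samples as `NA`, or supply `mask`).
#' @param stimulus A [stimulus_trace()].
#' @param mask Optional `exclusion_mask` on the eye-velocity grid.
#' @param use_nominal_amplitude Use the commanded peak velocity as the
#'   stimulus amplitude (default); `FALSE` uses a sine fit to the recorded
#'   stimulus velocity instead.
#' @param correct_window_attenuation Divide out the differentiation
#'   window's attenuation at the stimulus frequency (default `TRUE`).
#' @return A `gain_phase`: `frequency_hz`, `gain`, `phase_deg`, `fit_r2`.
#' @export
gain_phase <- function(eye_velocity, stimulus, mask = NULL,
                       use_nominal_amplitude = TRUE,
                       correct_window_attenuation = TRUE) {
  t <- eye_velocity$time_s; v <- eye_velocity$value
  if (!is.null(mask)) v[as.logical(mask)] <- NA_real_
  ef <- fit_sine(t, v, stimulus$frequency_hz)
  if (correct_window_attenuation && is.finite(eye_velocity$window_ms)) {
    att <- .slope_window_attenuation(stimulus$frequency_hz,
                                     eye_velocity$sample_rate_hz,
                                     eye_velocity$window_ms)
    ef$amplitude <- ef$amplitude / att
  }
  sf <- fit_sine(stimulus$time_s, stimulus$velocity_deg_s,
                 stimulus$frequency_hz)
  stim_amp <- if (use_nominal_amplitude) stimulus$peak_velocity_deg_s else sf$amplitude
  structure(
    list(frequency_hz = stimulus$frequency_hz,
         gain = ef$amplitude / stim_amp,
         phase_deg = .wrap180(ef$phase_deg - (sf$phase_deg + 180)),
         fit_r2 = ef$r2),
    class = "gain_phase"
  )
}

#' @export
print.gain_phase <- function(x, ...) {
  cat(sprintf("<gain_phase> %.3g Hz: gain %.3f, phase %.2f deg (r2 %.3f)\n",
              x$frequency_hz, x$gain, x$phase_deg, x$fit_r2))
  invisible(x)
}

#' Spatial resolution from stationary fixation epochs
#'
#' Finds disjoint epochs in which the eye is essentially stationary —
#' free of saccades (the 50 ms |velocity| never reaches the saccade
#' threshold) and free of net drift (the least-squares drift across the
#' whole epoch stays below `stationary_max_deg_s`) — takes the `n_epochs`
#' quietest ones (smallest |drift|), and reports the mean of the per-epoch
#' standard deviations of eye position about the epoch mean. Judging
#' stationarity on the epoch-level drift rather than the instantaneous
#' velocity keeps sub-sample measurement jitter, which is exactly the
#' quantity being measured, from disqualifying quiet epochs.
#'
#' @param eye An [eye_trace()].
#' @param n_epochs Number of epochs to average. Default 3.
#' @param epoch_s Epoch length (s). Default 2.
#' @param stationary_max_deg_s Drift criterion on the epoch least-squares
#'   slope (deg/s). Default 0.5.
#' @param saccade_threshold_deg_s Saccade exclusion threshold on the 50 ms
#'   |velocity| (deg/s). Default 50.
#' @return A list: `resolution_deg`, `epoch_starts_s`, `epoch_sds_deg`.
#' @export
spatial_resolution <- function(eye, n_epochs = 3, epoch_s = 2,
                               stationary_max_deg_s = 0.5,
                               saccade_threshold_deg_s = 50) {
  fs <- eye$sample_rate_hz
  len <- round(epoch_s * fs)
  vel <- differentiate(eye, 50)$value
  n_win <- floor(length(eye$position_deg) / len)
  if (n_win < n_epochs) {
    stop(sprintf("trace holds only %d epochs of %g s; %d required",
                 n_win, epoch_s, n_epochs), call. = FALSE)
  }
  tt <- (seq_len(len) - 1) / fs
  tt <- tt - mean(tt)
  stt <- sum(tt^2)
  stats_per <- t(vapply(seq_len(n_win), function(w) {
    idx <- ((w - 1) * len + 1):(w * len)
    p <- eye$position_deg[idx]
    c(maxv = max(abs(vel[idx]), na.rm = TRUE),
      drift = abs(sum(tt * (p - mean(p))) / stt),
      sd = stats::sd(p))
  }, numeric(3)))
  pass <- which(stats_per[, "drift"] < stationary_max_deg_s &
                  stats_per[, "maxv"] < saccade_threshold_deg_s)
  if (length(pass) < n_epochs) {
    stop(sprintf("only %d stationary epochs found; %d required",
                 length(pass), n_epochs), call. = FALSE)
  }
  sel <- pass[order(stats_per[pass, "drift"])][seq_len(n_epochs)]
  list(resolution_deg = mean(stats_per[sel, "sd"]),
       epoch_starts_s = eye$time_s[(sel - 1) * len + 1],
       epoch_sds_deg = unname(stats_per[sel, "sd"]))
}

#' Motion index of overhead video with Active/Still tertiles
#'
#' Subtracts the pixel-wise mean background from all frames, takes the mean
#' absolute difference between each frame and the next as the raw motion
#' trace, smooths it with a centered 2 s moving average, and labels the
#' upper third of smoothed values `Active` and the lower third `Still`
#' (ties broken by first occurrence).
#'
#' @param frames List of equally sized image matrices, or the list returned
#'   by [generate_overhead_motion()].
#' @param frame_rate_hz Frame rate (Hz); taken from the input list when
#'   present.
#' @param smooth_s Moving-average width (s). Default 2.
#' @return A `motion_index_trace`: data.frame `time_s`, `raw_motion`,
#'   `smoothed_motion`, `label` (one row per frame transition).
#' @export
motion_index <- function(frames, frame_rate_hz = NULL, smooth_s = 2) {
  if (is.list(frames) && !is.null(frames$frames)) {
    frame_rate_hz <- frame_rate_hz %||% frames$frame_rate_hz
    frames <- frames$frames
  }
  if (length(frames) < 2L) stop("at least 2 frames are required", call. = FALSE)
  if (is.null(frame_rate_hz)) stop("`frame_rate_hz` is required", call. = FALSE)
  bg <- Reduce(`+`, frames) / length(frames)
  sub <- lapply(frames, function(f) f - bg)
  n <- length(frames) - 1L
  raw <- vapply(seq_len(n), function(i) {
    mean(abs(sub[[i + 1L]] - sub[[i]]))
  }, numeric(1))
  half <- max(0L, round(smooth_s * frame_rate_hz / 2))
  smoothed <- vapply(seq_len(n), function(i) {
    mean(raw[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  k <- round(n / 3)
  rk <- rank(smoothed, ties.method = "first")
  label <- rep("Middle", n)
  label[rk <= k] <- "Still"
  label[rk > n - k] <- "Active"
  structure(
    data.frame(time_s = (seq_len(n) - 1) / frame_rate_hz,
               raw_motion = raw, smoothed_motion = smoothed, label = label),
    class = c("motion_index_trace", "data.frame"),
    frame_rate_hz = frame_rate_hz, smooth_s = smooth_s
  )
}

#' Binocular position, speed and divergence summary
#'
#' Both eye traces must share one time base and a common rightward-positive
#' convention. Position SD and mean speed are computed per eye and averaged
#' across the two eyes before reporting; divergence is the right-eye minus
#' left-eye angle. When behavioural labels are supplied the summary is also
#' broken out by `Active` and `Still`.
#'
#' @param left,right [eye_trace()]s in the common convention.
#' @param labels Optional character vector of per-sample behavioural labels
#'   (`"Active"`/`"Middle"`/`"Still"`), same length as the traces.
#' @param window_ms Differentiation window for speed (ms). Default 50.
#' @return A `binocular_summary`: data.frame with one row per condition and
#'   columns `condition`, `n`, `position_sd_deg`, `mean_speed_deg_s`,
#'   `divergence_mean_deg`, `divergence_sd_deg`.
#' @export
binocular_stats <- function(left, right, labels = NULL, window_ms = 50) {
  if (length(left$time_s) != length(right$time_s) ||
      max(abs(left$time_s - right$time_s)) > 1e-9) {
    stop("left and right eye traces must be time-aligned", call. = FALSE)
  }
  lv <- abs(differentiate(left, window_ms)$value)
  rv <- abs(differentiate(right, window_ms)$value)
  div <- right$position_deg - left$position_deg
  one <- function(idx, name) {
    data.frame(
      condition = name, n = length(idx),
      position_sd_deg = mean(c(stats::sd(left$position_deg[idx]),
                               stats::sd(right$position_deg[idx]))),
      mean_speed_deg_s = mean(c(mean(lv[idx], na.rm = TRUE),
                                mean(rv[idx], na.rm = TRUE))),
      divergence_mean_deg = mean(div[idx]),
      divergence_sd_deg = stats::sd(div[idx])
    )
  }
  out <- one(seq_along(div), "all")
  if (!is.null(labels)) {
    if (length(labels) != length(div)) {
      stop("`labels` must match the trace length", call. = FALSE)
    }
    for (cond in c("Active", "Still")) {
      idx <- which(labels == cond)
      if (length(idx) > 1L) out <- rbind(out, one(idx, cond))
    }
  }
  structure(out, class = c("binocular_summary", "data.frame"))
}

#' Eye-head velocity relation
#'
#' OLS slope of eye velocity on head yaw velocity plus the Pearson
#' correlation, on aligned desaccaded traces.
#'
#' @param eye_velocity,head_yaw_velocity Numeric vectors or
#'   [velocity_trace()]s of equal length (deg/s).
#' @return A list: `slope`, `intercept`, `r`, `n`.
#' @export
eye_head_relation <- function(eye_velocity, head_yaw_velocity) {
  ev <- if (inherits(eye_velocity, "velocity_trace")) eye_velocity$value else eye_velocity
  hv <- if (inherits(head_yaw_velocity, "velocity_trace")) head_yaw_velocity$value else head_yaw_velocity
  ok <- is.finite(ev) & is.finite(hv)
  ev <- ev[ok]; hv <- hv[ok]
  if (stats::sd(hv) == 0) {
    stop("head velocity is constant: slope undefined", call. = FALSE)
  }
  f <- stats::lm(ev ~ hv)
  list(slope = unname(stats::coef(f)[2]),
       intercept = unname(stats::coef(f)[1]),
       r = stats::cor(ev, hv), n = length(ev))
}
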