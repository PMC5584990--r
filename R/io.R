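# File dialects and the end-to-end pipeline. Time series travel as CSV with
# unit-suffixed column names (`_s`, `_deg`, `_mV`), structured outputs as
# JSON. Every output embeds the configuration hash and seeds so reruns are
# reproducible and diffable.

#' Read a columnar time series CSV
#'
#' The first column must be a strictly increasing, uniformly sampled time
#' column named with an `_s` suffix. Units are parsed from the column-name
#' suffixes (`_s` seconds, `_deg` degrees, `_deg_s` deg/s, `_mV`
#' millivolts).
#'
#' @param path CSV file path.
#' @param tolerance Allowed relative jitter of the sampling interval.
#' @return A data.frame with attributes `units` (named character) and
#'   `sample_rate_hz`.
#' @export
read_timeseries <- function(path, tolerance = 1e-4) {
  df <- utils::read.csv(path, check.names = FALSE)
  tcol <- names(df)[1]
  if (!grepl("_s$", tcol)) {
    stop("first column must be a time column with an `_s` suffix", call. = FALSE)
  }
  t <- df[[1]]
  d <- diff(t)
  if (any(d <= 0)) stop("time column must be strictly increasing", call. = FALSE)
  if ((max(d) - min(d)) > tolerance * stats::median(d) * 100) {
    stop("non-uniform sampling beyond tolerance", call. = FALSE)
  }
  units <- vapply(names(df), function(nm) {
    if (grepl("_deg_s$", nm)) "deg/s"
    else if (grepl("_mV_ms$", nm)) "mV/ms"
    else if (grepl("_deg$", nm)) "deg"
    else if (grepl("_mV$", nm)) "mV"
    else if (grepl("_s$", nm)) "s"
    else NA_character_
  }, character(1))
  if (any(is.na(units))) {
    stop("missing unit suffix on column(s): ",
         paste(names(df)[is.na(units)], collapse = ", "), call. = FALSE)
  }
  attr(df, "units") <- units
  attr(df, "sample_rate_hz") <- 1 / stats::median(d)
  df
}

#' Write a time series CSV
#'
#' @param df Data.frame whose first column is time in seconds.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic session to a directory
#'
#' Writes the observable streams of a [generate_session()] bundle as the
#' package's CSV dialects plus `truth.json` and `config.json` sidecars:
#' `stimulus.csv`, `sensor.csv`, `ttl.csv`, `camera_landmarks.csv`,
#' `camera_intensity.csv`.
#'
#' @param session A `session_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- session$stimulus
  write_timeseries(data.frame(time_s = st$time_s,
                              stimulus_deg = st$position_deg,
                              stimulus_vel_deg_s = st$velocity_deg_s),
                   file.path(dir, "stimulus.csv"))
  se <- session$sensor
  write_timeseries(data.frame(time_s = se$time_s,
                              ch1_mV = se$v_mV[, 1], ch2_mV = se$v_mV[, 2]),
                   file.path(dir, "sensor.csv"))
  utils::write.csv(data.frame(time_s = se$ttl_pulse_times_s),
                   file.path(dir, "ttl.csv"), row.names = FALSE)
  if (!is.null(session$camera)) {
    utils::write.csv(as.data.frame(session$camera)[
      , c("time_s", "cam", "pupil_x_px", "pupil_y_px",
          "cr_x_px", "cr_y_px", "valid")],
      file.path(dir, "camera_landmarks.csv"), row.names = FALSE)
    write_timeseries(session$camera_intensity,
                     file.path(dir, "camera_intensity.csv"))
  }
  truth <- list(k_true_deg_per_mV = session$truth$k_true,
                response_gain = session$truth$kinematics$response_gain,
                response_phase_deg = session$truth$kinematics$response_phase_deg,
                camera_latency_s = session$truth$camera_latency_s,
                seed = session$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- list(stimulus_frequency_hz = st$frequency_hz,
              peak_velocity_deg_s = st$peak_velocity_deg_s,
              sensor_sample_rate_hz = se$sample_rate_hz,
              rig = unclass(session$rig), r_p_mm = session$r_p_mm,
              geometry = unclass(session$geometry), seed = session$seed)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read / write grayscale frames as PNG
#'
#' Frames are `height x width` matrices in \[0, 1\]; color PNGs are
#' converted to grayscale by channel averaging on read.
#'
#' @param path PNG file path.
#' @param image Matrix in \[0, 1\].
#' @return `read_frame`: the image matrix. `write_frame`: `path`,
#'   invisibly.
#' @export
read_frame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}

#' @rdname read_frame
#' @export
write_frame <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Save / load a calibration as JSON
#'
#' @param calibration A `position_calibration` or `velocity_calibration`.
#' @param path JSON file path.
#' @return `path` (save) or the calibration object (load).
#' @export
save_calibration <- function(calibration, path) {
  obj <- unclass(calibration)
  obj$class <- class(calibration)[1]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$class
  obj$class <- NULL
  if (!is.null(obj$coefficients)) obj$coefficients <- as.list(obj$coefficients)
  structure(obj, class = cls)
}

#' Session configuration
#'
#' Validates a pipeline configuration against the documented schema;
#' unknown keys are rejected and every seed is explicit.
#'
#' @param session_dir Directory holding the session CSVs.
#' @param calibration_method `"position"` or `"velocity"`.
#' @param calibration_model `"one_channel"`, `"two_channel"` or
#'   `"quadratic"` (position method only).
#' @param stimulus_frequency_hz Stimulus frequency (Hz); read from the
#'   session `config.json` when `NULL`.
#' @param video_threshold_deg_s,magnet_threshold_mV_ms,pad_ms Desaccading
#'   thresholds and padding.
#' @param window_ms Differentiation window (ms).
#' @param n_folds Cross-validation blocks for ridge models.
#' @param seed Integer seed for every stochastic step.
#' @param positive_toward_cam2 Sign convention of the video-derived angle.
#' @return A validated `session_config` list.
#' @export
session_config <- function(session_dir,
                           calibration_method = c("position", "velocity"),
                           calibration_model = c("one_channel",
                                                 "two_channel", "quadratic"),
                           stimulus_frequency_hz = NULL,
                           video_threshold_deg_s = 50,
                           magnet_threshold_mV_ms = 5,
                           pad_ms = 50, window_ms = 50, n_folds = 10,
                           seed = 1L, positive_toward_cam2 = TRUE) {
  structure(
    list(session_dir = session_dir,
         calibration_method = match.arg(calibration_method),
         calibration_model = match.arg(calibration_model),
         stimulus_frequency_hz = stimulus_frequency_hz,
         video_threshold_deg_s = video_threshold_deg_s,
         magnet_threshold_mV_ms = magnet_threshold_mV_ms,
         pad_ms = pad_ms, window_ms = window_ms, n_folds = n_folds,
         seed = as.integer(seed),
         positive_toward_cam2 = isTRUE(positive_toward_cam2)),
    class = "session_config"
  )
}

#' Validate a configuration read from JSON
#'
#' @param x A named list (e.g. from `jsonlite::read_json`).
#' @return A `session_config`; unknown keys raise an error.
#' @export
as_session_config <- function(x) {
  known <- names(formals(session_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(session_config, x)
}

# stable polynomial hash of a config, for provenance stamping only
.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full calibration-and-analysis pipeline on a session directory
#'
#' Stages, each logged with its parameters and record counts: read the
#' streams; per-frame eye position from the dual-camera landmarks; LED
#' flash detection and video/sensor alignment; desaccading with the union
#' mask; calibration by the configured method; application of the
#' calibration; gain/phase of the calibrated eye-velocity response. Writes
#' `calibration.json` and `report.json` (no timestamps, so reruns with the
#' same inputs and seeds are byte-identical).
#'
#' @param config A `session_config`, or a path to a JSON file encoding one.
#' @param output_dir Where to write outputs. Default: the session
#'   directory.
#' @param verbose Print stage logs. Default `FALSE`.
#' @return The report, invisibly (a named list).
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = FALSE) {
  if (is.character(config)) {
    config <- as_session_config(jsonlite::read_json(config,
                                                    simplifyVector = TRUE))
  }
  if (!inherits(config, "session_config")) {
    stop("`config` must be a session_config or a JSON path", call. = FALSE)
  }
  dir <- config$session_dir
  output_dir <- output_dir %||% dir
  say <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage `%s` failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }

  inp <- stage("read", {
    scfg <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
    sens <- read_timeseries(file.path(dir, "sensor.csv"))
    ttl <- utils::read.csv(file.path(dir, "ttl.csv"))$time_s
    stim_df <- read_timeseries(file.path(dir, "stimulus.csv"))
    lmk <- utils::read.csv(file.path(dir, "camera_landmarks.csv"))
    inten <- utils::read.csv(file.path(dir, "camera_intensity.csv"))
    list(scfg = scfg, sens = sens, ttl = ttl, stim = stim_df, lmk = lmk,
         inten = inten)
  })
  freq <- config$stimulus_frequency_hz %||% inp$scfg$stimulus_frequency_hz
  say("read", "%d sensor samples, %d landmarks, %d TTL pulses, f = %g Hz",
      nrow(inp$sens), nrow(inp$lmk), length(inp$ttl), freq)

  rig <- stage("geometry", do.call(camera_rig, inp$scfg$rig))
  sensor <- sensor_trace(inp$sens$time_s,
                         cbind(inp$sens$ch1_mV, inp$sens$ch2_mV),
                         ttl_pulse_times_s = inp$ttl)
  stim <- stimulus_trace(inp$stim$time_s, inp$stim$stimulus_deg,
                         inp$stim$stimulus_vel_deg_s, freq,
                         inp$scfg$peak_velocity_deg_s)
  video_eye <- stage("geometry", {
    fr <- pupil_frames(inp$lmk, rig)
    eye_position_from_frames(fr, rig, config$positive_toward_cam2)
  })
  say("geometry", "%d video frames -> eye position", length(video_eye$time_s))

  al <- stage("align", {
    onsets <- detect_sync_flash(inp$inten$mean_intensity)
    flash_t <- inp$inten$time_s[onsets]
    ev <- differentiate(video_eye, config$window_ms)
    vmask <- detect_artifacts(ev, config$video_threshold_deg_s,
                              config$pad_ms, source = "video")
    mv <- differentiate(sensor, config$window_ms)
    smask <- mask_union(
      detect_artifacts(mv$ch1, config$magnet_threshold_mV_ms,
                       config$pad_ms, source = "sensor"),
      detect_artifacts(mv$ch2, config$magnet_threshold_mV_ms,
                       config$pad_ms, source = "sensor"))
    align_streams(video_eye, flash_t, sensor, video_mask = vmask,
                  sensor_mask = smask)
  })
  say("align", "offset %.4g s, drift %.6g, %d samples excluded",
      al$clock_offset_s, al$clock_drift, sum(al$excluded))

  calib <- stage("calibrate", {
    if (config$calibration_method == "velocity") {
      fit_velocity_calibration(video_eye, sensor, freq,
                               config$video_threshold_deg_s,
                               config$magnet_threshold_mV_ms,
                               config$window_ms)
    } else {
      switch(config$calibration_model,
        one_channel = fit_position_one_channel(al),
        two_channel = fit_position_two_channel(al, n_folds = config$n_folds,
                                               seed = config$seed),
        quadratic = fit_position_quadratic(al, n_folds = config$n_folds,
                                           seed = config$seed))
    }
  })

  report <- stage("analyze", {
    k <- if (inherits(calib, "velocity_calibration")) calib$factor else {
      if (calib$model == "one_channel") calib$k else calib$coefficients$k1
    }
    cal_eye <- if (inherits(calib, "velocity_calibration")) {
      mv <- differentiate(sensor, config$window_ms)
      ch <- calib$chosen_channel
      apply_calibration(mv[[ch]], calib)
    } else {
      differentiate(apply_calibration(sensor, calib), config$window_ms)
    }
    cmask <- detect_artifacts(cal_eye, config$video_threshold_deg_s,
                              config$pad_ms, source = "calibrated")
    gp <- gain_phase(cal_eye, stim, mask = cmask)
    list(
      config_hash = .config_hash(unclass(config)),
      seed = config$seed,
      calibration_method = config$calibration_method,
      calibration_model = if (inherits(calib, "velocity_calibration"))
        "velocity" else calib$model,
      calibration_factor_deg_per_mV = k,
      n_samples = length(al$time_s), n_excluded = sum(al$excluded),
      clock_offset_s = al$clock_offset_s, clock_drift = al$clock_drift,
      gain = gp$gain, phase_deg = gp$phase_deg, fit_r2 = gp$fit_r2,
      stimulus_frequency_hz = freq
    )
  })
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  save_calibration(calib, file.path(output_dir, "calibration.json"))
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  say("analyze", "gain %.3f, phase %.2f deg, k %.5g deg/mV",
      report$gain, report$phase_deg, report$calibration_factor_deg_per_mV)
  invisible(report)
}
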