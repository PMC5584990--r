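# Dual-angle video-oculography geometry. Two cameras view the eye with their
# axes 40 deg apart; the signed horizontal pupil-to-CR distance in camera i is
# Delta_i = Rp * sin(theta_i), where theta_i is the angle from that camera's
# axis to the pupil axis and Rp the pupil-plane to corneal-curvature-center
# distance. The ratio of the two distances eliminates Rp, so eye angle is
# recovered without knowing it.

#' Dual-camera rig description
#'
#' @param inter_camera_angle_deg Angle between the two camera axes (deg),
#'   strictly between 0 and 90. Default 40.
#' @param camera_distance_mm Lens-to-axis-intersection distance (mm),
#'   default 50. Both lenses are equidistant so the two images share one
#'   spatial scale.
#' @param pixel_scale_mm_per_px Image magnification (mm per pixel).
#' @return An object of class `camera_rig`.
#' @export
camera_rig <- function(inter_camera_angle_deg = 40,
                       camera_distance_mm = 50,
                       pixel_scale_mm_per_px = 0.0125) {
  if (inter_camera_angle_deg <= 0 || inter_camera_angle_deg >= 90) {
    stop("`inter_camera_angle_deg` must lie in (0, 90)", call. = FALSE)
  }
  if (camera_distance_mm <= 0) stop("`camera_distance_mm` must be positive", call. = FALSE)
  if (pixel_scale_mm_per_px <= 0) stop("`pixel_scale_mm_per_px` must be positive", call. = FALSE)
  structure(
    list(inter_camera_angle_deg = inter_camera_angle_deg,
         camera_distance_mm = camera_distance_mm,
         pixel_scale_mm_per_px = pixel_scale_mm_per_px),
    class = "camera_rig"
  )
}

#' Eye angle from the two pupil-CR distances
#'
#' Inverts the dual-angle projection. With camera angle `alpha`,
#' `Delta1 = Rp sin(alpha - theta2)` and `Delta2 = Rp sin(theta2)`, so
#' `theta2 = atan2(Delta2 sin(alpha), Delta1 + Delta2 cos(alpha))` — the
#' two-argument arctangent form of the ratio formula. It is algebraically
#' identical to `atan(sin(alpha) / (Delta1/Delta2 + cos(alpha)))` where
#' `Delta2 > 0`, but stays defined at `Delta2 = 0` and for signed distances,
#' and is independent of `Rp`.
#'
#' @param delta1_mm Signed horizontal pupil-CR distance in camera 1 (mm).
#' @param delta2_mm Same for camera 2 (mm). Vectors are paired.
#' @param rig A [camera_rig()].
#' @return `theta2` in degrees (angle from camera 2's axis to the pupil axis).
#' @examples
#' angle_from_deltas(0.342, 0.342)  # symmetric pupil -> 20 deg
#' @export
angle_from_deltas <- function(delta1_mm, delta2_mm, rig = camera_rig()) {
  if (any(delta1_mm == 0 & delta2_mm == 0)) {
    stop("both distances zero: eye angle undefined", call. = FALSE)
  }
  a <- rig$inter_camera_angle_deg * pi / 180
  atan2(delta2_mm * sin(a), delta1_mm + delta2_mm * cos(a)) * 180 / pi
}

#' Forward projection of an eye angle into pupil-CR distances
#'
#' Exact forward model: `Delta1 = Rp sin(alpha - theta2)`,
#' `Delta2 = Rp sin(theta2)`, with signed values for angles beyond either
#' camera axis. Inverse of [angle_from_deltas()] up to floating point.
#'
#' @param theta2_deg Angle from camera 2's axis to the pupil axis (deg).
#' @param r_p_mm Pupil-plane to corneal-curvature-center distance (mm), > 0.
#' @param rig A [camera_rig()].
#' @return A two-column matrix `delta1_mm`, `delta2_mm`.
#' @export
forward_deltas <- function(theta2_deg, r_p_mm = 1.25, rig = camera_rig()) {
  if (any(r_p_mm <= 0)) stop("`r_p_mm` must be positive", call. = FALSE)
  a <- rig$inter_camera_angle_deg
  cbind(delta1_mm = r_p_mm * sin((a - theta2_deg) * pi / 180),
        delta2_mm = r_p_mm * sin(theta2_deg * pi / 180))
}

#' Pupil/CR landmark series from the two cameras
#'
#' One row per frame per camera: pupil and reference-CR pixel coordinates,
#' the signed horizontal pupil-CR distance in pixels and millimetres, and a
#' validity flag. Invalid frames are excluded from downstream fits.
#'
#' @param df A data.frame with columns `time_s`, `cam` (1 or 2),
#'   `pupil_x_px`, `pupil_y_px`, `cr_x_px`, `cr_y_px`, `valid` (logical).
#' @param rig The [camera_rig()] used, stored to convert px to mm.
#' @return An object of class `pupil_frames` (a data.frame with extra
#'   columns `delta_px`, `delta_mm` and the rig in an attribute).
#' @export
pupil_frames <- function(df, rig = camera_rig()) {
  need <- c("time_s", "cam", "pupil_x_px", "pupil_y_px", "cr_x_px",
            "cr_y_px", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing landmark columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(df$cam %in% c(1L, 2L))) stop("`cam` must be 1 or 2", call. = FALSE)
  df$delta_px <- df$pupil_x_px - df$cr_x_px
  df$delta_mm <- df$delta_px * rig$pixel_scale_mm_per_px
  structure(df, class = c("pupil_frames", "data.frame"), rig = rig)
}

#' Per-frame eye position from dual-camera landmarks
#'
#' Pairs the two cameras' signed distances frame by frame, applies
#' [angle_from_deltas()] and reports the angle in the symmetric-zero
#' convention: 0 degrees on the bisector of the two camera axes (the rig is
#' aligned so the resting pupil sits roughly between the two CRs), i.e.
#' `theta2 - alpha/2`, optionally sign-flipped to match the eye's
#' nasal/temporal convention. Frames invalid in either camera yield `NA`.
#'
#' @param frames A [pupil_frames()] series.
#' @param rig A [camera_rig()]; defaults to the rig stored in `frames`.
#' @param positive_toward_cam2 Logical sign convention flag: `TRUE` (default)
#'   reports angles increasing toward camera 2.
#' @return An [eye_trace()] (invalid frames as `NA` positions are kept in a
#'   plain list result when any frame is invalid).
#' @export
eye_position_from_frames <- function(frames, rig = attr(frames, "rig"),
                                     positive_toward_cam2 = TRUE) {
  f1 <- frames[frames$cam == 1L, ]
  f2 <- frames[frames$cam == 2L, ]
  if (nrow(f1) != nrow(f2) || any(abs(f1$time_s - f2$time_s) > 1e-9)) {
    stop("cameras 1 and 2 must supply matching frame times", call. = FALSE)
  }
  ok <- f1$valid & f2$valid
  if (!any(ok)) stop("all frames invalid", call. = FALSE)
  ang <- rep(NA_real_, nrow(f1))
  ang[ok] <- angle_from_deltas(f1$delta_mm[ok], f2$delta_mm[ok], rig) -
    rig$inter_camera_angle_deg / 2
  if (!positive_toward_cam2) ang <- -ang
  if (all(ok)) {
    eye_trace(f1$time_s, ang)
  } else {
    structure(list(time_s = f1$time_s, position_deg = ang,
                   sample_rate_hz = 1 / stats::median(diff(f1$time_s))),
              class = "eye_trace")
  }
}
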