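#' Motorised table motion profile
#'
#' Parameters of the passive recumbent flexion protocol: the motorised
#' trunk section of the table accelerates at `accel` deg/s^2, moves at the
#' constant `plateau_velocity` until the gross trunk flexion reaches
#' `max_angle`, decelerates at the same rate, and (optionally) returns
#' along the mirrored profile.  Frames are sampled at `frame_rate` Hz.
#' The defaults are the published protocol: 6 deg/s^2 for 1 s, 6 deg/s
#' plateau, 40 deg maximum flexion, 15 Hz imaging.
#'
#' @param accel angular acceleration, deg/s^2 (> 0).
#' @param plateau_velocity constant-phase angular velocity, deg/s (> 0).
#' @param max_angle gross flexion excursion, deg.  Must be at least
#'   `plateau_velocity^2 / accel` so the acceleration and deceleration
#'   ramps fit inside the excursion.
#' @param frame_rate sampling rate, Hz (> 0).
#' @param include_return if `TRUE` (default) the mirrored return phase is
#'   appended after the outward phase.
#'
#' @return An object of class `table_profile`.
#' @export
table_profile <- function(accel = 6, plateau_velocity = 6, max_angle = 40,
                          frame_rate = 15, include_return = TRUE) {
  assert_number(accel, "accel", lower = 0, strict_lower = TRUE)
  assert_number(plateau_velocity, "plateau_velocity", lower = 0, strict_lower = TRUE)
  assert_number(max_angle, "max_angle", lower = 0, strict_lower = TRUE)
  assert_number(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  ramp <- plateau_velocity^2 / accel  # angle covered by accel + decel together
  if (max_angle < ramp - 1e-12)
    stop(sprintf(paste0("infeasible table profile: acceleration and deceleration ",
                        "phases cover %.3f deg which exceeds max_angle = %.3f deg"),
                 ramp, max_angle))
  structure(
    list(accel = accel, plateau_velocity = plateau_velocity,
         max_angle = max_angle, frame_rate = frame_rate,
         include_return = isTRUE(include_return)),
    class = "table_profile")
}

#' @export
print.table_profile <- function(x, ...) {
  ph <- table_phase_times(x)
  cat("<table_profile>\n")
  cat(sprintf("  accel %.3g deg/s^2, plateau %.3g deg/s, max %.3g deg, %g Hz\n",
              x$accel, x$plateau_velocity, x$max_angle, x$frame_rate))
  cat(sprintf("  outward duration %.4g s%s\n", ph$t_out,
              if (x$include_return) sprintf(", total %.4g s with return", 2 * ph$t_out)
              else " (no return)"))
  invisible(x)
}

## Phase boundary times of the outward motion (seconds).
table_phase_times <- function(profile) {
  t_acc <- profile$plateau_velocity / profile$accel
  d_acc <- profile$plateau_velocity^2 / (2 * profile$accel)
  d_plateau <- profile$max_angle - 2 * d_acc
  t_plateau <- d_plateau / profile$plateau_velocity
  t_out <- 2 * t_acc + t_plateau
  list(t_acc = t_acc, d_acc = d_acc, t_plateau = t_plateau, t_out = t_out)
}

## Closed-form gross angle of the outward motion at times t (vectorised).
table_angle_outward <- function(t, profile) {
  ph <- table_phase_times(profile)
  a <- profile$accel
  v <- profile$plateau_velocity
  ang <- numeric(length(t))
  acc <- t <= ph$t_acc
  ang[acc] <- 0.5 * a * t[acc]^2
  mid <- t > ph$t_acc & t <= ph$t_acc + ph$t_plateau
  ang[mid] <- ph$d_acc + v * (t[mid] - ph$t_acc)
  dec <- t > ph$t_acc + ph$t_plateau
  ang[dec] <- profile$max_angle - 0.5 * a * pmax(ph$t_out - t[dec], 0)^2
  ang
}

#' Generate the gross table motion as a motion sequence skeleton
#'
#' Samples the piecewise trapezoidal-velocity table profile at the frame
#' rate: quadratic rise during acceleration, linear during the plateau,
#' mirrored deceleration into the peak, and (if `include_return`) the
#' time-reversed return.  The continuous profile peaks exactly at
#' `max_angle`; with the default parameters the peak lies on the frame grid.
#'
#' @param profile a [table_profile()].
#' @return A [motion_sequence()] with `gross_deg` filled in and no level
#'   angles (a skeleton for [generate_subject()]).
#' @export
generate_table_motion <- function(profile) {
  stopifnot(inherits(profile, "table_profile"))
  ph <- table_phase_times(profile)
  t_total <- if (profile$include_return) 2 * ph$t_out else ph$t_out
  n_frames <- floor(t_total * profile$frame_rate + 1e-9) + 1L
  t <- (seq_len(n_frames) - 1L) / profile$frame_rate
  outward <- t <= ph$t_out + 1e-12
  ang <- numeric(n_frames)
  ang[outward] <- table_angle_outward(t[outward], profile)
  ang[!outward] <- table_angle_outward(2 * ph$t_out - t[!outward], profile)
  motion_sequence(t, ang,
                  phase = ifelse(outward, "outward", "return"),
                  meta = list(profile = unclass(profile),
                              t_outward = ph$t_out))
}
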