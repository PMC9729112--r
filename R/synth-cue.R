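#' Closed-loop visual cue stream
#'
#' In closed loop the cue azimuth is yoked to the fly's own rotation: the cue
#' rotates with the fly at matched velocity, so
#' `cue[k] = wrap(offset0 + heading[k])`. A cue position of 0 deg means the
#' cue is directly in front of the fly; 180 deg is directly behind.
#'
#' @param traj an `fc_trajectory` from [gen_walking_trajectory()].
#' @param offset0 initial cue azimuth in degrees.
#' @return data frame of class `fc_angle_series` with columns `t` and
#'   `angle` (degrees in `[0, 360)`).
#' @export
gen_closed_loop_cue <- function(traj, offset0 = 0) {
  stopifnot(is.data.frame(traj), all(c("t", "heading") %in% names(traj)))
  structure(data.frame(t = traj$t, angle = wrap360(offset0 + traj$heading)),
            class = c("fc_angle_series", "data.frame"))
}

#' Open-loop visual cue stream
#'
#' A constant-velocity wrapped ramp (the standard rotating-bar protocol, about
#' 18 deg/s), with each full 360-degree rotation annotated as a cycle.
#'
#' @param duration_s duration in seconds.
#' @param rate_hz sampling rate in Hz.
#' @param speed rotation speed in deg/s (non-negative).
#' @param direction `"right"` (increasing azimuth) or `"left"`.
#' @param start_deg starting azimuth in degrees.
#' @return data frame of class `fc_angle_series` with columns `t`, `angle`
#'   and `cycle_id` (integer, 1-based; constant 1 when `speed` is 0).
#' @export
gen_open_loop_cue <- function(duration_s, rate_hz, speed = 18,
                              direction = c("right", "left"),
                              start_deg = 0) {
  direction <- match.arg(direction)
  stopifnot(duration_s > 0, rate_hz > 0, speed >= 0)
  t <- seq(0, duration_s, by = 1 / rate_hz)
  t <- t[t < duration_s]
  sgn <- if (direction == "right") 1 else -1
  unwrapped <- sgn * speed * t
  cycle_id <- if (speed > 0) floor(abs(unwrapped) / 360) + 1L else
    rep(1L, length(t))
  structure(data.frame(t = t, angle = wrap360(start_deg + unwrapped),
                       cycle_id = as.integer(cycle_id)),
            class = c("fc_angle_series", "data.frame"),
            speed_deg_s = sgn * speed)
}

#' Cycle boundary times of an annotated angle series
#' @param cue an `fc_angle_series` with a `cycle_id` column.
#' @return times at which a new full rotation begins (excluding the first).
#' @export
cue_cycle_boundaries <- function(cue) {
  stopifnot("cycle_id" %in% names(cue))
  cue$t[which(diff(cue$cycle_id) > 0) + 1]
}

#' Mark samples where the cue is hidden behind the fly
#'
#' The fly cannot see the cue at azimuths between 150 and 210 degrees;
#' analyses of offset and mutual information exclude these samples.
#'
#' @param angle cue azimuths in degrees.
#' @return logical vector, `TRUE` where hidden.
#' @export
cue_hidden <- function(angle) {
  a <- wrap360(angle)
  a > 150 & a < 210
}
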