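#' Synthetic ExR2-like dF/F signal
#'
#' ExR2 dopamine-neuron activity is modelled as linearly coupled to the fly's
#' rotational speed with a fixed lag:
#' `dff[t] = slope * |rot_velocity(t - lag)| + fwd_gain * fwd_velocity(t) +
#' noise`. The true slope, lag and forward gain are attached as ground truth
#' for recovery tests.
#'
#' @param traj an `fc_trajectory`.
#' @param cfg a [synth_config()]; uses `exr2_slope`, `exr2_lag_s`, `noise_sd`.
#' @param fwd_gain optional dF/F per mm/s forward-speed coupling (default 0).
#' @return data frame of class `fc_dff_series` with columns `t`, `dff`;
#'   attribute `truth` holds `slope`, `lag_s` and `fwd_gain`.
#' @export
gen_exr2_dff <- function(traj, cfg, fwd_gain = 0) {
  stopifnot(inherits(cfg, "synth_config"), is.data.frame(traj))
  n <- nrow(traj)
  lag_samp <- round(cfg$exr2_lag_s * cfg$sample_rate_hz)
  speed <- abs(traj$rot_velocity)
  lagged <- if (lag_samp > 0) {
    c(rep(speed[1], lag_samp), speed[seq_len(n - lag_samp)])
  } else speed
  with_seed(cfg$seed + 101L, {
    dff <- cfg$exr2_slope * lagged + fwd_gain * traj$fwd_velocity +
      rnorm(n, sd = cfg$noise_sd)
    structure(data.frame(t = traj$t, dff = dff),
              class = c("fc_dff_series", "data.frame"),
              truth = list(slope = cfg$exr2_slope, lag_s = cfg$exr2_lag_s,
                           fwd_gain = fwd_gain),
              sample_rate_hz = cfg$sample_rate_hz)
  })
}

#' Synthetic eight-wedge EPG bump fluorescence
#'
#' Emulates volumetric calcium imaging of the ellipsoid body: a von Mises
#' bump of dF/F across the 8 wedge ROIs whose phase follows a reference angle
#' (cue or heading) with fidelity set by `coupling`. At `coupling = 1` the
#' bump phase tracks the reference exactly; at `coupling = 0` it performs an
#' independent circular random walk. Intermediate values place the phase
#' part-way along the shortest arc from the reference towards the walk. Bump
#' amplitude is `1 + amp_speed_gain * |rot_velocity|`, emulating the
#' speed-amplitude coupling abolished by hyperpolarizing ExR2.
#'
#' @param ref an `fc_angle_series` giving the reference angle (cue azimuth or
#'   heading) on the behavioural grid.
#' @param traj the matching `fc_trajectory` (for rotational speed).
#' @param cfg a [synth_config()]; uses `bump_kappa`, `amp_speed_gain`,
#'   `noise_sd`, `seed`.
#' @param volume_rate_hz imaging volume rate in Hz (6-9 Hz typical).
#' @param coupling tracking fidelity in `[0, 1]`.
#' @param coupling2,step_at_s optional: switch the coupling to `coupling2` at
#'   time `step_at_s`, emulating an abrupt gain of cue control (as after
#'   dopamine-neuron stimulation).
#' @param phase_walk_sd innovation SD of the independent phase walk, degrees
#'   per volume. The default mixes around the circle within tens of seconds,
#'   like an untethered bump drifting in darkness.
#' @return data frame of class `fc_wedge_series` with columns `t` and
#'   `w1..w8`; attributes `volume_rate_hz`, `wedge_centers` and `truth`
#'   (latent `phase`, `amplitude`, `coupling`, interpolated `rot_speed`).
#' @export
gen_epg_wedges <- function(ref, traj, cfg, volume_rate_hz = 6.7,
                           coupling = 1, coupling2 = NULL, step_at_s = NULL,
                           phase_walk_sd = 30) {
  stopifnot(inherits(cfg, "synth_config"))
  if (any(c(coupling, coupling2) < 0) || any(c(coupling, coupling2) > 1)) {
    stop("coupling must be in [0, 1]")
  }
  if (volume_rate_hz <= 0) stop("volume_rate_hz must be positive")
  tv <- seq(0, max(ref$t), by = 1 / volume_rate_hz)
  ref_v <- approx(ref$t, unwrap_deg(ref$angle), xout = tv, rule = 2)$y
  speed_v <- approx(traj$t, abs(traj$rot_velocity), xout = tv, rule = 2)$y
  nv <- length(tv)
  centers <- seq(0, 315, by = 45)

  cpl <- rep(coupling, nv)
  if (!is.null(coupling2)) {
    if (is.null(step_at_s)) stop("step_at_s is required with coupling2")
    cpl[tv >= step_at_s] <- coupling2
  }

  with_seed(cfg$seed + 202L, {
    walk <- wrap360(cumsum(c(ref_v[1] %% 360, rnorm(nv - 1, sd = phase_walk_sd))))
    phase <- wrap360(ref_v + (1 - cpl) * circ_dist_deg(walk, wrap360(ref_v)))
    amplitude <- 1 + cfg$amp_speed_gain * speed_v
    prof <- outer(phase, centers, function(p, ctr) {
      vm <- exp(cfg$bump_kappa * cos(deg2rad(p - ctr)))
      vm
    })
    # scale each row so the bump spans [0, amplitude] across wedges
    lo <- exp(-cfg$bump_kappa); hi <- exp(cfg$bump_kappa)
    prof <- (prof - lo) / (hi - lo) * amplitude
    dff <- prof + matrix(rnorm(nv * 8, sd = cfg$noise_sd), nv, 8)
    out <- data.frame(t = tv, dff)
    names(out) <- c("t", paste0("w", 1:8))
    structure(out, class = c("fc_wedge_series", "data.frame"),
              volume_rate_hz = volume_rate_hz, wedge_centers = centers,
              truth = list(phase = phase, amplitude = amplitude,
                           coupling = cpl, rot_speed = speed_v))
  })
}

# cumulative unwrapped angle (degrees) from a wrapped series
unwrap_deg <- function(a) {
  d <- circ_dist_deg(a[-1], a[-length(a)])
  cumsum(c(a[1], d))
}
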