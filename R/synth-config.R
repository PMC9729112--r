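#' Configuration for the synthetic-data generators
#'
#' Bundles every knob the generators share. Defaults emulate a fly walking on
#' a spherical treadmill tracked at ~60 Hz, with alternating rest, fixation
#' (straight walking with near-constant heading) and turning epochs, plus an
#' ExR2-like dopamine signal linearly coupled to rotational speed with a
#' ~300 ms lag.
#'
#' @param seed integer RNG seed; the same seed gives bit-identical output.
#' @param duration_s total duration in seconds.
#' @param sample_rate_hz behavioural sampling rate (Hz).
#' @param rest_fraction,fixation_fraction expected fraction of time spent
#'   resting / walking straight while fixating a heading; their sum must be
#'   at most 1, the remainder is turning.
#' @param rot_speed_scale stationary SD of rotational velocity during turning
#'   epochs (deg/s).
#' @param fwd_speed_scale mean forward speed while walking (mm/s).
#' @param exr2_slope ExR2 dF/F per deg/s of rotational speed.
#' @param exr2_lag_s lag of the ExR2 signal behind rotational speed (s).
#' @param bump_kappa von Mises concentration of the synthetic calcium bump
#'   across the 8 wedges.
#' @param amp_speed_gain bump-amplitude gain, dF/F per deg/s.
#' @param noise_sd per-channel additive Gaussian noise SD.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         duration_s = 600,
                         sample_rate_hz = 60,
                         rest_fraction = 0.3,
                         fixation_fraction = 0.3,
                         rot_speed_scale = 60,
                         fwd_speed_scale = 8,
                         exr2_slope = 0.01,
                         exr2_lag_s = 0.3,
                         bump_kappa = 2,
                         amp_speed_gain = 0.005,
                         noise_sd = 0.05) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            duration_s > 0, sample_rate_hz > 0,
            rest_fraction >= 0, fixation_fraction >= 0,
            rot_speed_scale >= 0, fwd_speed_scale >= 0,
            bump_kappa > 0, noise_sd >= 0, exr2_lag_s >= 0)
  if (rest_fraction + fixation_fraction > 1) {
    stop("rest_fraction + fixation_fraction must be <= 1")
  }
  if (duration_s * sample_rate_hz < 10) {
    stop("invalid config: duration shorter than 10 samples")
  }
  structure(list(seed = as.integer(seed), duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz,
                 rest_fraction = rest_fraction,
                 fixation_fraction = fixation_fraction,
                 rot_speed_scale = rot_speed_scale,
                 fwd_speed_scale = fwd_speed_scale,
                 exr2_slope = exr2_slope, exr2_lag_s = exr2_lag_s,
                 bump_kappa = bump_kappa, amp_speed_gain = amp_speed_gain,
                 noise_sd = noise_sd),
            class = "synth_config")
}
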