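# biexponential spike template, ~3 ms wide, unit peak
spike_template <- function(fs, rise_s = 0.0005, decay_s = 0.001,
                           width_s = 0.003) {
  tt <- seq(0, width_s, by = 1 / fs)
  w <- (1 - exp(-tt / rise_s)) * exp(-tt / decay_s)
  w / max(w)
}

#' Synthetic single-cell voltage recording under a rotating cue
#'
#' Membrane voltage is a ~-55 mV baseline plus cosine tuning to the cue
#' azimuth, stereotyped spike waveforms whose rate is modulated by the same
#' tuning, and Gaussian noise. The preferred azimuth can be remapped abruptly
#' at a given cycle, emulating the jump in preferred cue position seen after
#' dopamine-neuron stimulation.
#'
#' @param preferred preferred cue azimuth in degrees.
#' @param cycles number of full cue rotations to simulate; `cue` must contain
#'   at least this many annotated cycles.
#' @param cue an `fc_angle_series` with `cycle_id` (see
#'   [gen_open_loop_cue()]).
#' @param amp_mV peak tuning amplitude in mV.
#' @param spike_rate_hz mean spike rate at the preferred azimuth in Hz
#'   (instantaneous rate `spike_rate_hz * (1 + cos(cue - preferred)) / 2 * 2`
#'   is cosine-modulated; 0 disables spiking).
#' @param noise_sd voltage noise SD in mV.
#' @param remap_at_cycle,new_preferred optional abrupt change of the
#'   preferred azimuth from the start of cycle `remap_at_cycle`.
#' @param fs_hz output sampling rate in Hz.
#' @param spike_amp_mV spike peak above baseline, mV.
#' @param baseline_mV resting potential, mV.
#' @param seed RNG seed.
#' @return data frame of class `fc_cycle_recording` with columns `t`,
#'   `voltage` (mV), `cue` (deg) and `cycle_id`; attributes `fs_hz`, `arena`
#'   (`"full_360"`) and `truth` (spike times, per-cycle preferred azimuth).
#' @export
gen_voltage_trace <- function(preferred, cycles, cue, amp_mV = 5,
                              spike_rate_hz = 0, noise_sd = 0.5,
                              remap_at_cycle = NULL, new_preferred = NULL,
                              fs_hz = 10000, spike_amp_mV = 40,
                              baseline_mV = -55, seed = 1L) {
  stopifnot("cycle_id" %in% names(cue))
  if (max(cue$cycle_id) < cycles) stop("cue does not contain enough cycles")
  cue <- cue[cue$cycle_id <= cycles, ]
  t_end <- max(cue$t) + diff(cue$t[1:2])
  t <- seq(0, t_end, by = 1 / fs_hz)
  t <- t[t < t_end]
  cue_t <- approx(cue$t, unwrap_deg(cue$angle), xout = t, rule = 2)$y
  cyc_t <- as.integer(approx(cue$t, cue$cycle_id, xout = t,
                             method = "constant", rule = 2)$y)
  pref_by_cycle <- rep(preferred, cycles)
  if (!is.null(remap_at_cycle)) {
    if (is.null(new_preferred)) stop("new_preferred required with remap_at_cycle")
    pref_by_cycle[seq(remap_at_cycle, cycles)] <- new_preferred
  }
  pref_t <- pref_by_cycle[cyc_t]

  with_seed(seed, {
    tuning <- cos(deg2rad(cue_t - pref_t))
    v <- baseline_mV + amp_mV * tuning + rnorm(length(t), sd = noise_sd)
    spike_times <- numeric(0)
    if (spike_rate_hz > 0) {
      rate <- spike_rate_hz * (1 + tuning)  # mean = spike_rate_hz over a cycle
      fire <- rbinom(length(t), 1, pmin(1, rate / fs_hz)) == 1
      # enforce a 5 ms minimum separation so ground truth is unambiguous
      st <- t[fire]
      if (length(st) > 1) st <- st[c(TRUE, diff(st) > 0.005)]
      spike_times <- st
      tpl <- spike_template(fs_hz)
      for (s in spike_times) {
        i0 <- round(s * fs_hz) + 1
        idx <- i0:min(length(v), i0 + length(tpl) - 1)
        v[idx] <- v[idx] + spike_amp_mV * tpl[seq_along(idx)]
      }
    }
    structure(data.frame(t = t, voltage = v, cue = wrap360(cue_t),
                         cycle_id = cyc_t),
              class = c("fc_cycle_recording", "data.frame"),
              fs_hz = fs_hz, arena = "full_360",
              truth = list(spike_times = spike_times,
                           preferred_by_cycle = pref_by_cycle))
  })
}
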