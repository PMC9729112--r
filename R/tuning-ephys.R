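# 270-degree arena <-> full-circle rescaling. The asymmetric panorama spans
# arena coordinates -123.75 to +146.25 deg; tuning vectors are computed after
# stretching that span onto 0-360 deg, then mapped back.
arena_to_circle <- function(a) (a + 123.75) / 270 * 360
circle_to_arena <- function(th) wrap360(th) / 360 * 270 - 123.75

#' Preferred cue position of one cue-rotation cycle from membrane voltage
#'
#' The voltage is resampled onto a uniform grid of cue angles over the full
#' arena sweep and the vector phase
#' `atan2(sum(V sin(theta)), sum(V cos(theta)))` computed; on a uniform grid
#' the constant (resting-potential) component cancels exactly. For the
#' asymmetric 270-degree arena, cue positions are rescaled to 0-360 deg
#' before the sum and the phase mapped back to arena coordinates.
#'
#' @param cue cue positions of the cycle, degrees (arena coordinates).
#' @param voltage matching membrane voltage, mV.
#' @param arena `"full_360"` or `"asym_270"`.
#' @param n_grid uniform resampling grid size.
#' @return preferred cue position in degrees (arena coordinates).
#' @export
vector_phase_voltage <- function(cue, voltage, arena = c("full_360", "asym_270"),
                                 n_grid = 360) {
  arena <- match.arg(arena)
  stopifnot(length(cue) == length(voltage))
  th <- if (arena == "asym_270") arena_to_circle(cue) else wrap360(cue)
  span <- diff(range(th))
  if (span < 300) stop("incomplete cycle: cue sweep covers only ", round(span), " deg")
  grid <- seq(0, 360 - 360 / n_grid, by = 360 / n_grid)
  ord <- order(th)
  Vg <- approx(th[ord], voltage[ord], xout = grid, rule = 2, ties = mean)$y
  s <- sum(Vg * sin(deg2rad(grid))); c <- sum(Vg * cos(deg2rad(grid)))
  if (sqrt(s^2 + c^2) / max(sum(abs(Vg)), 1e-12) < 1e-10) {
    stop("undefined vector phase: untuned (constant) voltage")
  }
  ph <- wrap360(rad2deg(atan2(s, c)))
  if (arena == "asym_270") circle_to_arena(ph) else ph
}

#' Preferred cue position from spike-triggered cue angles
#'
#' Vector phase of the cue positions present at spike times:
#' `atan2(sum(sin theta), sum(cos theta))`.
#'
#' @param spike_cue_angles cue positions at spike times, degrees.
#' @return preferred cue position in degrees.
#' @export
vector_phase_spikes <- function(spike_cue_angles) {
  if (length(spike_cue_angles) == 0) stop("no spikes")
  th <- deg2rad(spike_cue_angles)
  s <- sum(sin(th)); c <- sum(cos(th))
  if (sqrt(s^2 + c^2) / length(th) < 1e-10) {
    stop("undefined vector phase: balanced spike angles")
  }
  wrap360(rad2deg(atan2(s, c)))
}

#' Per-cycle preferred cue positions of a recording
#'
#' @param rec an `fc_cycle_recording`.
#' @return data frame with `cycle_id`, `t_mid` (s), `preferred` (deg).
#' @export
cycle_preferred <- function(rec) {
  arena <- attr(rec, "arena")
  if (is.null(arena)) arena <- "full_360"
  out <- lapply(split(rec, rec$cycle_id), function(d) {
    data.frame(cycle_id = d$cycle_id[1], t_mid = mean(range(d$t)),
               preferred = vector_phase_voltage(d$cue, d$voltage, arena))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Circular dispersion of per-cycle preferred positions in a time window
#'
#' @param preferred per-cycle preferred positions, degrees.
#' @param t_mid matching cycle times (s); omit to use all cycles.
#' @param window length-2 time interval (s).
#' @return circular standard deviation in degrees (`Inf` for a uniform
#'   sample).
#' @export
circ_dispersion <- function(preferred, t_mid = NULL, window = NULL) {
  if (!is.null(window)) {
    stopifnot(!is.null(t_mid))
    preferred <- preferred[t_mid >= window[1] & t_mid < window[2]]
  }
  if (length(preferred) < 2) stop("need at least 2 cycles in the window")
  circ_sd_deg(preferred)
}

#' Watson-Williams comparison of pre vs post preferred positions
#'
#' Two-sample Watson-Williams F-test with Bonferroni correction for the
#' number of cells tested; following the reporting convention for such
#' screens, the corrected p-value is returned uncapped (it can exceed 1).
#'
#' @param pre,post angle samples in degrees.
#' @param n_comparisons Bonferroni multiplier.
#' @return list: `p_corrected` (uncapped), `p_raw`, `F`, `low_concentration`.
#' @export
watson_williams <- function(pre, post, n_comparisons = 1) {
  ww <- watson_williams_test(pre, post)
  list(p_corrected = ww$p * n_comparisons, p_raw = ww$p, F = ww$F,
       low_concentration = ww$low_concentration)
}

#' Rayleigh gate for baseline tuning
#'
#' Cells whose baseline-window preferred positions fail the Rayleigh
#' uniformity test (p >= alpha) are labelled untuned and excluded from
#' preferred-position change statistics (their preferred position is not a
#' meaningful value).
#'
#' @param preferred_by_cycle baseline-window preferred positions, degrees.
#' @param alpha significance threshold.
#' @return list: `tuned` (logical), `p`.
#' @export
rayleigh_gate <- function(preferred_by_cycle, alpha = 0.05) {
  rt <- rayleigh_test(preferred_by_cycle)
  list(tuned = rt$p < alpha, p = rt$p)
}

#' Visual response amplitude per cue-rotation cycle
#'
#' The voltage is median-filtered (running median over `filt_window_s`,
#' which suppresses brief spikes) and the per-cycle amplitude is the
#' filtered maximum minus minimum.
#'
#' @param rec an `fc_cycle_recording`.
#' @param filt_window_s median-filter window in seconds.
#' @return data frame with `cycle_id`, `t_mid`, `amp_mV`.
#' @export
response_amplitude <- function(rec, filt_window_s = 0.100) {
  fs <- attr(rec, "fs_hz")
  if (is.null(fs)) fs <- 1 / median(diff(rec$t))
  kk <- max(3L, round(filt_window_s * fs))
  if (kk %% 2 == 0) kk <- kk + 1L
  vf <- runmed(rec$voltage, kk, endrule = "median")
  out <- lapply(split(seq_len(nrow(rec)), rec$cycle_id), function(idx) {
    data.frame(cycle_id = rec$cycle_id[idx[1]],
               t_mid = mean(range(rec$t[idx])),
               amp_mV = max(vf[idx]) - min(vf[idx]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Normalize per-cycle response amplitudes to a baseline window
#'
#' @param amps data frame from [response_amplitude()].
#' @param baseline_window length-2 time interval (s).
#' @return `amps` with an extra `amp_norm` column.
#' @export
normalize_amplitude <- function(amps, baseline_window) {
  base <- amps$amp_mV[amps$t_mid >= baseline_window[1] &
                        amps$t_mid < baseline_window[2]]
  if (length(base) == 0) stop("no cycles in the baseline window")
  amps$amp_norm <- amps$amp_mV / mean(base)
  amps
}

#' Bin a time series into fixed-width time bins (means)
#'
#' @param t times (s); `x` matching values.
#' @param x values.
#' @param bin_s bin width in seconds.
#' @return data frame with `t` (bin centre) and `mean`.
#' @export
bin_mean <- function(t, x, bin_s = 40) {
  b <- floor(t / bin_s)
  data.frame(t = (sort(unique(b)) + 0.5) * bin_s,
             mean = vapply(split(x, b), mean, numeric(1)))
}

#' Derivative-threshold spike detection
#'
#' The voltage (optionally inverted) is low-pass filtered with a digital
#' Butterworth filter, differentiated, and candidate events taken where the
#' derivative peaks above `deriv_threshold`. An event is kept if the
#' low-pass-filtered deflection around it is wider than `min_width_s` at its
#' base (10% of the local peak above baseline — the full spike waveform, so
#' a ~3 ms spike passes a 2.5 ms gate while sub-millisecond glitches fail),
#' and if it follows the previous accepted event by more than `refractory_s`.
#'
#' @param voltage voltage trace, mV.
#' @param fs sampling rate, Hz.
#' @param lp_cutoff low-pass cutoff, Hz (must be below Nyquist).
#' @param deriv_threshold threshold on the derivative (mV per sample).
#' @param min_width_s minimum event width at half-peak, s.
#' @param refractory_s minimum separation between events, s.
#' @param invert multiply the trace by -1 first (downward spikes).
#' @param butter_order Butterworth filter order.
#' @return spike times in seconds (relative to the first sample).
#' @export
detect_spikes_deriv <- function(voltage, fs, lp_cutoff = 500,
                                deriv_threshold = 2,
                                min_width_s = 0.0025, refractory_s = 0.002,
                                invert = FALSE, butter_order = 2) {
  if (lp_cutoff >= fs / 2) stop("lp_cutoff must be below the Nyquist frequency")
  v <- if (invert) -voltage else voltage
  bf <- signal::butter(butter_order, lp_cutoff / (fs / 2), type = "low")
  vf <- as.numeric(signal::filtfilt(bf, v - v[1])) + v[1]
  dv <- c(0, diff(vf))
  above <- dv > deriv_threshold
  if (!any(above)) return(numeric(0))
  # candidate peaks: maximum derivative within each suprathreshold run
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- integer(0)
  for (i in which(runs$values)) {
    seg <- starts[i]:ends[i]
    cand <- c(cand, seg[which.max(dv[seg])])
  }
  base <- median(vf)
  width_ok <- vapply(cand, function(i0) {
    # width of the filtered deflection at 10% of its local peak
    look <- max(1, i0 - round(0.01 * fs)):min(length(vf), i0 + round(0.01 * fs))
    pk <- max(vf[look])
    lev <- base + (pk - base) * 0.1
    above <- vf[look] > lev
    ip <- which.max(vf[look])
    left <- ip
    while (left > 1 && above[left - 1]) left <- left - 1
    right <- ip
    while (right < length(above) && above[right + 1]) right <- right + 1
    (right - left + 1) / fs > min_width_s
  }, logical(1))
  cand <- cand[width_ok]
  if (length(cand) == 0) return(numeric(0))
  keep <- cand[1]
  for (i in cand[-1]) {
    if ((i - tail(keep, 1)) / fs > refractory_s) keep <- c(keep, i)
  }
  (keep - 1) / fs
}

#' Coincidence-gated EPG spike detection from paired channels
#'
#' Candidate events are transients in the amplifier current channel
#' (deviation beyond `curr_thresh_mad` robust SDs). A candidate is counted
#' as a spike only if a voltage fluctuation wider than `width_s` occurs
#' within `coincidence_s` of it, and the peak voltage of that fluctuation is
#' in the top `top_frac` of voltage values for the trial.
#'
#' @param current amplifier current trace.
#' @param voltage voltage trace, mV.
#' @param fs sampling rate, Hz.
#' @param curr_thresh_mad current-transient threshold in MADs.
#' @param width_s minimum voltage-fluctuation width, s.
#' @param coincidence_s maximum current-voltage separation, s.
#' @param top_frac required upper quantile of the fluctuation peak.
#' @return spike times in seconds.
#' @export
detect_spikes_epg <- function(current, voltage, fs, curr_thresh_mad = 5,
                              width_s = 0.0015, coincidence_s = 0.0015,
                              top_frac = 0.15) {
  stopifnot(length(current) == length(voltage))
  dev <- abs(current - median(current))
  thr <- curr_thresh_mad * mad(current)
  above <- dev > thr
  if (!any(above)) return(numeric(0))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- integer(0)
  for (i in which(runs$values)) {
    seg <- starts[i]:ends[i]
    cand <- c(cand, seg[which.max(dev[seg])])
  }
  # voltage fluctuations: excursions above a robust baseline band
  vdev <- voltage - runmed(voltage, 2 * floor(0.025 * fs) + 1)
  vthr <- 2 * mad(vdev)
  vabove <- vdev > vthr
  vruns <- rle(vabove)
  vends <- cumsum(vruns$lengths)
  vstarts <- vends - vruns$lengths + 1
  fl_start <- vstarts[vruns$values]; fl_end <- vends[vruns$values]
  fl_w <- (fl_end - fl_start + 1) / fs
  fl_peak <- mapply(function(a, b) max(voltage[a:b]), fl_start, fl_end)
  vq <- quantile(voltage, 1 - top_frac, names = FALSE)
  good <- fl_w > width_s & fl_peak >= vq
  fl_start <- fl_start[good]; fl_end <- fl_end[good]
  tol <- round(coincidence_s * fs)
  hits <- vapply(cand, function(i0) {
    any(fl_start - tol <= i0 & fl_end + tol >= i0)
  }, logical(1))
  (cand[hits] - 1) / fs
}

#' Peristimulus time histogram of spike rate
#'
#' @param spike_times spike times in seconds.
#' @param bin_s bin width in seconds.
#' @param window length-2 interval (s) to histogram over.
#' @return data frame with `t` (bin centre) and `rate_hz`.
#' @export
psth <- function(spike_times, bin_s = 5, window) {
  edges <- seq(window[1], window[2], by = bin_s)
  if (length(edges) < 2) stop("window shorter than one bin")
  counts <- vapply(seq_len(length(edges) - 1), function(i) {
    sum(spike_times >= edges[i] & spike_times < edges[i + 1])
  }, numeric(1))
  data.frame(t = edges[-length(edges)] + bin_s / 2, rate_hz = counts / bin_s)
}
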