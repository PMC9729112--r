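test_that("voltage vector phase recovers analytic cosine tuning and cancels
           the resting potential", {
  th <- seq(0, 359.5, by = 0.5)
  V <- -55 + cos((th - 30) * pi / 180)
  expect_lt(abs(circ_dist_deg(vector_phase_voltage(th, V), 30)), 1)
  # adding a constant changes nothing on a uniform full sweep
  expect_equal(vector_phase_voltage(th, V + 20),
               vector_phase_voltage(th, V), tolerance = 1e-6)
  expect_error(vector_phase_voltage(th, rep(-55, length(th))), "untuned")
  expect_error(vector_phase_voltage(th[1:100], V[1:100]), "incomplete")
})

test_that("270-degree arena rescaling round-trips and recovers a peak at
           arena coordinate 0", {
  x <- c(-123.75, -60, 0, 80, 146)  # interior of the half-open arena span
  expect_equal(flycompass:::circle_to_arena(flycompass:::arena_to_circle(x)),
               x, tolerance = 1e-9)
  th_arena <- seq(-123.75, 146.25, length.out = 721)
  th_circ <- flycompass:::arena_to_circle(th_arena)
  V <- -50 + cos((th_circ - flycompass:::arena_to_circle(0)) * pi / 180)
  got <- vector_phase_voltage(th_arena, V, arena = "asym_270")
  expect_lt(abs(got - 0), 1)
})

test_that("spike vector phase follows the spike-triggered cue angles", {
  expect_equal(vector_phase_spikes(rep(90, 7)), 90)
  expect_equal(vector_phase_spikes(c(0, 90)), 45)
  expect_error(vector_phase_spikes(c(0, 180)), "balanced")
  expect_error(vector_phase_spikes(numeric(0)), "no spikes")
})

test_that("circular dispersion: degenerate cases and the von Mises closed
           form", {
  expect_equal(circ_dispersion(rep(42, 10)), 0)
  expect_true(is.infinite(circ_dispersion(c(0, 90, 180, 270))))
  set.seed(40)
  kap <- 10
  sd_obs <- median(replicate(20, circ_sd_deg(rvonmises(50, 100, kap))))
  sd_exp <- sqrt(-2 * log(besselI(kap, 1) / besselI(kap, 0))) * 180 / pi
  expect_lt(abs(sd_obs - sd_exp) / sd_exp, 0.15)
  # windowing selects the right cycles
  pref <- c(10, 12, 11, 90, 95, 100)
  tm <- c(1, 2, 3, 11, 12, 13)
  expect_lt(circ_dispersion(pref, tm, window = c(0, 10)), 2)
})

test_that("Watson-Williams wrapper applies uncapped Bonferroni correction", {
  set.seed(41)
  a <- rvonmises(30, 20, 20)
  b <- rvonmises(30, 110, 20)
  ww <- watson_williams(a, b, n_comparisons = 11)
  expect_lt(ww$p_corrected, 0.001)
  same <- watson_williams(a, a + 0.5, n_comparisons = 11)
  expect_gt(same$p_corrected, 1)  # reported uncapped, as in screens
  expect_equal(same$p_corrected, same$p_raw * 11)
})

test_that("Rayleigh gate separates tuned from untuned cells", {
  set.seed(42)
  expect_true(rayleigh_gate(rvonmises(20, 70, 8))$tuned)
  expect_false(rayleigh_gate(seq(0, 351, by = 9))$tuned)
})

test_that("response amplitude: sinusoid peak-to-peak, spike suppression by
           the median filter, and flat traces", {
  fs <- 2000
  cue <- gen_open_loop_cue(40.01, 60, speed = 18)
  rec <- gen_voltage_trace(0, 2, cue, amp_mV = 5, spike_rate_hz = 0,
                           noise_sd = 0, fs_hz = fs)
  amps <- response_amplitude(rec)
  expect_equal(amps$amp_mV, rep(10, 2), tolerance = 0.05)
  rec_sp <- gen_voltage_trace(0, 2, cue, amp_mV = 5, spike_rate_hz = 5,
                              noise_sd = 0, fs_hz = fs, spike_amp_mV = 40,
                              seed = 5)
  amps_sp <- response_amplitude(rec_sp)
  expect_lt(max(abs(amps_sp$amp_mV - 10)) / 10, 0.05)
  flat <- rec
  flat$voltage <- rep(-55, nrow(flat))
  expect_equal(response_amplitude(flat)$amp_mV, rep(0, 2))
  # normalization to a baseline window
  normed <- normalize_amplitude(amps, baseline_window = c(0, 20))
  expect_equal(normed$amp_norm[1], amps$amp_mV[1] / amps$amp_mV[1])
})

test_that("40-s binning averages per bin", {
  b <- bin_mean(c(1, 2, 50, 70, 90), c(1, 3, 10, 20, 30), bin_s = 40)
  expect_equal(unname(b$mean), c(2, 15, 30))
  expect_equal(b$t, c(20, 60, 100))
})

test_that("derivative spike detection: exact recovery at high SNR,
           refractory and width gates", {
  fs <- 10000
  tpl <- flycompass:::spike_template(fs)
  n <- fs * 2
  base <- rep(-55, n)
  truth <- c(0.2, 0.5, 0.8, 1.1, 1.3, 1.5, 1.62, 1.8, 1.9, 1.95)
  v <- base
  for (s in truth) {
    i0 <- round(s * fs) + 1
    idx <- i0:(i0 + length(tpl) - 1)
    v[idx] <- v[idx] + 40 * tpl
  }
  set.seed(50)
  v_noisy <- v + rnorm(n, sd = 4)  # SNR 10
  det <- detect_spikes_deriv(v_noisy, fs)
  expect_equal(length(det), 10)
  expect_true(all(vapply(truth, function(s) any(abs(det - s) < 0.002),
                         logical(1))))
  # flat trace: nothing detected
  expect_length(detect_spikes_deriv(rep(-55, n), fs), 0)
  # two spikes 1 ms apart merge into one detection (2 ms refractory)
  v2 <- rep(-55, fs)
  for (s in c(0.5, 0.501)) {
    i0 <- round(s * fs) + 1
    idx <- i0:(i0 + length(tpl) - 1)
    v2[idx] <- v2[idx] + 40 * tpl[seq_along(idx)]
  }
  expect_length(detect_spikes_deriv(v2, fs), 1)
  # a sub-millisecond glitch fails the 2.5 ms width gate
  v3 <- rep(-55, fs)
  v3[5000:5003] <- -55 + 40
  expect_length(detect_spikes_deriv(v3, fs), 0)
  expect_error(detect_spikes_deriv(v3, fs, lp_cutoff = 6000), "Nyquist")
})

test_that("detection F1 stays above 0.95 at generator SNR >= 8", {
  fs <- 10000
  cue <- gen_open_loop_cue(60.01, 60, speed = 18)
  rec <- gen_voltage_trace(0, 3, cue, amp_mV = 5, spike_rate_hz = 3,
                           noise_sd = 5, fs_hz = fs, spike_amp_mV = 40,
                           seed = 6)  # peak/noise = 8
  truth <- attr(rec, "truth")$spike_times
  det <- detect_spikes_deriv(rec$voltage, fs)
  tp <- sum(vapply(truth, function(s) any(abs(det - s) < 0.002), logical(1)))
  prec <- tp / max(length(det), 1)
  rec_ <- tp / length(truth)
  f1 <- 2 * prec * rec_ / (prec + rec_)
  expect_gte(f1, 0.95)
})

test_that("coincidence-gated EPG detection applies all three criteria", {
  fs <- 10000
  n <- fs
  set.seed(51)
  curr <- rnorm(n, sd = 0.5)
  # baseline with a slow tuning sweep, so the top-15% voltage gate is
  # anchored by real modulation rather than noise
  volt <- -55 + 5 * cos(2 * pi * seq_len(n) / n) + rnorm(n, sd = 0.5)
  # a genuine spike: current transient + wide voltage fluctuation with a
  # high peak
  i0 <- 3000
  curr[i0:(i0 + 5)] <- 20
  volt[(i0 - 10):(i0 + 25)] <- volt[(i0 - 10):(i0 + 25)] + 25
  # current transient with no voltage fluctuation
  curr[6000:6005] <- 20
  # current transient with a low-amplitude (50th percentile) fluctuation
  i2 <- 8000
  curr[i2:(i2 + 5)] <- 20
  volt[(i2 - 10):(i2 + 25)] <- volt[(i2 - 10):(i2 + 25)] + 2
  det <- detect_spikes_epg(curr, volt, fs)
  expect_length(det, 1)
  expect_lt(abs(det - (i0 - 1) / fs), 0.002)
})

test_that("PSTH converts spike counts to rates per bin", {
  p0 <- psth(numeric(0), bin_s = 5, window = c(0, 20))
  expect_true(all(p0$rate_hz == 0))
  p1 <- psth(runif(25, 5, 10), bin_s = 5, window = c(0, 20))
  expect_equal(p1$rate_hz[2], 5)
  set.seed(52)
  spikes <- cumsum(rexp(400, rate = 2))
  spikes <- spikes[spikes < 100]
  p2 <- psth(spikes, bin_s = 5, window = c(0, 100))
  expect_lt(abs(mean(p2$rate_hz) - 2), 0.3)
})
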