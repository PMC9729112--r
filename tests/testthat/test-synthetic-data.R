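test_that("generators are deterministic given the seed and validate input", {
  cfg <- quick_cfg(seed = 7)
  t1 <- gen_walking_trajectory(cfg)
  t2 <- gen_walking_trajectory(cfg)
  expect_identical(t1, t2)
  expect_error(synth_config(rest_fraction = 0.7, fixation_fraction = 0.5),
               "<= 1")
  expect_error(synth_config(duration_s = 0.05), "10 samples")
})

test_that("trajectory honours the degenerate zero-rotation scale", {
  cfg <- quick_cfg(rot_speed_scale = 0)
  tr <- gen_walking_trajectory(cfg)
  expect_true(all(tr$rot_velocity == 0))
  expect_true(all(tr$heading == tr$heading[1]))
})

test_that("realized rest fraction tracks the configured fraction", {
  cfg <- synth_config(seed = 5, duration_s = 600, rest_fraction = 0.5,
                      fixation_fraction = 0.2)
  tr <- gen_walking_trajectory(cfg)
  rest_like <- abs(tr$rot_velocity) < 15 & tr$fwd_velocity < 2
  expect_gte(mean(rest_like), 0.4)
  expect_lte(mean(rest_like), 0.6)
  # ground-truth labels agree with the configuration even more tightly
  expect_lt(abs(mean(tr$state == "rest") - 0.5), 0.15)
})

test_that("closed-loop cue is yoked to heading", {
  tr0 <- const_rot_traj(0, 10)
  cue0 <- gen_closed_loop_cue(tr0, offset0 = 42)
  expect_true(all(cue0$angle == 42))
  # constant 18 deg/s for 20 s completes one revolution
  tr18 <- const_rot_traj(18, 20)
  cue <- gen_closed_loop_cue(tr18, offset0 = 0)
  expect_lt(abs(circ_dist_deg(tail(cue$angle, 1), 0)), 1)
  # a heading ramp 0 -> 90 maps to a cue ramp offset0 -> offset0 + 90
  ramp <- data.frame(t = seq(0, 1, by = 0.1), heading = seq(0, 90, by = 9))
  cue_r <- gen_closed_loop_cue(ramp, offset0 = 30)
  expect_equal(cue_r$angle, wrap360(30 + ramp$heading))
})

test_that("open-loop cue is a wrapped ramp with annotated cycles", {
  cue <- gen_open_loop_cue(20, 60, speed = 18)
  expect_equal(max(cue$cycle_id), 1L)  # 360/18 = 20 s per rotation
  expect_length(cue_cycle_boundaries(cue), 0)
  cue2 <- gen_open_loop_cue(60.01, 60, speed = 36)
  expect_length(cue_cycle_boundaries(cue2), 6)
  cue0 <- gen_open_loop_cue(10, 60, speed = 0)
  expect_true(all(cue0$angle == cue0$angle[1]))
  expect_equal(max(cue0$cycle_id), 1L)
  left <- gen_open_loop_cue(5, 60, speed = 18, direction = "left")
  expect_lt(circ_dist_deg(left$angle[10], left$angle[1]), 0)
})

test_that("hidden-cue window covers 150-210 degrees exclusively", {
  expect_equal(cue_hidden(c(149, 151, 180, 209, 211, 0)),
               c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("ExR2 generator produces a lagged linear speed coupling", {
  cfg <- synth_config(seed = 3, duration_s = 120, noise_sd = 0,
                      exr2_lag_s = 0, exr2_slope = 0.02)
  tr <- gen_walking_trajectory(cfg)
  sig <- gen_exr2_dff(tr, cfg)
  expect_equal(sig$dff, 0.02 * abs(tr$rot_velocity), tolerance = 1e-12)
  # lagged version: cross-correlation peaks at the configured lag
  cfg2 <- synth_config(seed = 3, duration_s = 300, noise_sd = 0.02,
                       exr2_lag_s = 0.3)
  tr2 <- gen_walking_trajectory(cfg2)
  sig2 <- gen_exr2_dff(tr2, cfg2)
  lags <- 0:40
  cc <- vapply(lags, function(L) {
    n <- nrow(tr2)
    cor(sig2$dff[(L + 1):n], abs(tr2$rot_velocity)[1:(n - L)])
  }, numeric(1))
  expect_equal(lags[which.max(cc)] / cfg2$sample_rate_hz, 0.3,
               tolerance = 0.02)
  # zero slope: pure noise, no recoverable speed relation
  cfg3 <- synth_config(seed = 3, duration_s = 300, exr2_slope = 0)
  sig3 <- gen_exr2_dff(tr2, cfg3)
  fit <- summary(lm(sig3$dff ~ abs(tr2$rot_velocity)))
  expect_lt(fit$r.squared, 0.02)
})

test_that("wedge generator: perfect coupling reproduces the reference phase,
           zero coupling decouples it", {
  cfg <- synth_config(seed = 4, duration_s = 240, noise_sd = 0)
  tr <- gen_walking_trajectory(cfg)
  cue <- gen_closed_loop_cue(tr, 0)
  w1 <- gen_epg_wedges(cue, tr, cfg, coupling = 1)
  b1 <- bump_series(w1)
  ref <- attr(w1, "truth")$phase
  err <- abs(circ_dist_deg(b1$phase, ref))
  expect_lt(median(err, na.rm = TRUE), 22.5)  # half-wedge quantization
  # coupling 0: bump phase independent of the cue. The estimate keeps a
  # small positive bias from temporal autocorrelation of the phase walk,
  # so compare against the locked-bump value rather than exactly zero.
  w0 <- gen_epg_wedges(cue, tr, cfg, coupling = 0)
  b0 <- bump_series(w0)
  cue_v <- approx(cue$t, flycompass:::unwrap_deg(cue$angle),
                  xout = b0$t, rule = 2)$y
  ok <- !is.na(b0$phase)
  mi0 <- ksg_mi(circular_embed(wrap360(cue_v[ok])), circular_embed(b0$phase[ok]))
  ok1 <- !is.na(b1$phase)
  mi1 <- ksg_mi(circular_embed(wrap360(cue_v[ok1])), circular_embed(b1$phase[ok1]))
  expect_lt(mi0$mi, 0.4)
  expect_gt(mi1$mi, mi0$mi + 1.5)
  expect_error(gen_epg_wedges(cue, tr, cfg, coupling = 1.2), "coupling")
})

test_that("wedge generator: amplitude-speed gain of zero gives no
           amplitude-speed correlation", {
  cfg <- synth_config(seed = 6, duration_s = 240, amp_speed_gain = 0,
                      noise_sd = 0.02)
  tr <- gen_walking_trajectory(cfg)
  cue <- gen_closed_loop_cue(tr, 0)
  w <- gen_epg_wedges(cue, tr, cfg, coupling = 1)
  b <- bump_series(w)
  spd <- attr(w, "truth")$rot_speed
  expect_lt(abs(cor(b$amplitude, spd)), 0.08)
})

test_that("voltage generator: noise-free cosine tuning recovers the exact
           preferred angle, remap shifts it by the programmed amount", {
  cue <- gen_open_loop_cue(80.01, 60, speed = 18)
  rec <- gen_voltage_trace(preferred = 60, cycles = 4, cue = cue,
                           amp_mV = 6, spike_rate_hz = 0, noise_sd = 0,
                           fs_hz = 2000)
  prefs <- cycle_preferred(rec)
  expect_lt(max(abs(circ_dist_deg(prefs$preferred, 60))), 1)
  rec2 <- gen_voltage_trace(preferred = 60, cycles = 8,
                            cue = gen_open_loop_cue(160.01, 60, speed = 18),
                            amp_mV = 6, spike_rate_hz = 0, noise_sd = 0.2,
                            remap_at_cycle = 5, new_preferred = 120,
                            fs_hz = 2000, seed = 2)
  pr <- cycle_preferred(rec2)
  pre <- circ_mean_deg(pr$preferred[pr$cycle_id < 5])
  post <- circ_mean_deg(pr$preferred[pr$cycle_id >= 5])
  expect_lt(abs(abs(circ_dist_deg(post, pre)) - 60), 2)
  # untuned cell: per-cycle phases fail the Rayleigh test
  rec3 <- gen_voltage_trace(preferred = 60, cycles = 8,
                            cue = gen_open_loop_cue(160.01, 60, speed = 18),
                            amp_mV = 0, spike_rate_hz = 0, noise_sd = 0.5,
                            fs_hz = 2000, seed = 3)
  pr3 <- cycle_preferred(rec3)
  expect_false(rayleigh_gate(pr3$preferred)$tuned)
})
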