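test_that("visual drive is a rescaled von Mises profile over the ER ring", {
  p <- ring_params()
  vi <- visual_input(90, p)
  m_pref <- which.min(abs(circ_dist_deg(vi$prefs, 90)))
  expect_equal(vi$g[m_pref], p$g_max)          # peak pinned to g_max = 0.35
  m_opp <- which.min(abs(circ_dist_deg(vi$prefs, 270)))
  expect_equal(vi$g[m_opp], 0)                 # antipode zeroed
  expect_true(all(vi$g >= 0 & vi$g <= p$g_max))
  # flat limit: kappa -> 0 gives an all-zero drive after min subtraction
  p0 <- ring_params(); p0$kappa <- 1e-9
  expect_lt(max(visual_input(0, p0)$g), 1e-6)
})

test_that("one compiled step equals the scalar reference implementation", {
  p <- ring_params(n_epg = 8, n_er = 8)
  set.seed(10)
  f <- runif(8, 0, 0.5)
  W <- matrix(runif(64, 0, p$w_max), 8, 8)
  g <- visual_input(30, p)$g
  v <- 0.4
  eta <- 0.02
  f_ref <- step_dynamics(f, W, v, g, p)
  W_ref <- hebbian_update(W, f_ref, g, eta, p)
  res <- flycompass:::run_ring_raw(v, 30, TRUE, p, W, f, eta = eta, stride = 1L)
  expect_equal(as.numeric(res$f_final), f_ref, tolerance = 1e-12)
  expect_equal(unname(res$W_final), unname(W_ref), tolerance = 1e-12)
  # presynaptic variant agrees with its reference too
  pp <- ring_params(n_epg = 8, n_er = 8, learning_gate = "presynaptic")
  W_pre <- presynaptic_update(W, f_ref, g, eta, pp)
  res2 <- flycompass:::run_ring_raw(v, 30, TRUE, pp, W, f, eta = eta, stride = 1L)
  expect_equal(unname(res2$W_final), unname(W_pre), tolerance = 1e-12)
})

test_that("rate dynamics: constant drive from zero state, rectification and
           non-positive visual input", {
  p <- ring_params()
  f0 <- rep(0, p$n_epg)
  W0 <- matrix(0, p$n_epg, p$n_er)
  g <- visual_input(0, p)$g
  f1 <- step_dynamics(f0, W0, 0, g, p)
  # bracket reduces to [+1]_+ = 1, so every neuron rises by dt/tau
  expect_equal(f1, rep(p$dt / p$tau, p$n_epg), tolerance = 1e-12)
  # I_n <= 0 whenever noise is absent: weights and drive are non-negative
  set.seed(11)
  W <- matrix(runif(p$n_epg * p$n_er, 0, p$w_max), p$n_epg, p$n_er)
  expect_true(all(-as.numeric(W %*% g) <= 0))
  # rates stay non-negative across random steps
  f <- runif(p$n_epg, 0, 2)
  for (i in 1:50) f <- step_dynamics(f, W, 2, g, p)
  expect_true(all(f >= 0))
})

test_that("v = 0 with a symmetric rate profile preserves the symmetry axis", {
  p <- ring_params(n_epg = 4, n_er = 4)
  # profile symmetric about neuron 1: f2 = f4
  f <- c(1, 0.5, 0.2, 0.5)
  W <- matrix(0, 4, 4)
  g <- rep(0, 4)
  for (i in 1:20) f <- step_dynamics(f, W, 0, g, p)
  expect_equal(f[2], f[4], tolerance = 1e-12)
})

test_that("adaptive learning rate is proportional to unsigned velocity and
           the matched fixed rate equals its mean", {
  p <- ring_params(eta_gain = 0.5)
  expect_equal(adaptive_eta(0, p), 0)
  expect_equal(adaptive_eta(2, p), 1)
  expect_equal(adaptive_eta(-2, p), 1)
  cfg <- quick_cfg(seed = 2, duration_s = 120)
  tr <- gen_walking_trajectory(cfg)
  pa <- ring_params(eta_mode = "adaptive", seed = 2)
  pf <- ring_params(eta_mode = "fixed", seed = 2)
  sa <- run_simulation(tr, pa, stride_s = 30)
  sf <- run_simulation(tr, pf, stride_s = 30)
  expect_equal(sf$eta_mean, sa$eta_mean, tolerance = 1e-12)
})

test_that("Hebbian rule: gating by postsynaptic activity, fixed point, and a
           hand-computed update", {
  p <- ring_params(n_epg = 4, n_er = 4)
  W <- matrix(0.1, 4, 4)
  g <- c(0.3, 0.1, 0, 0.2)
  # silent postsynaptic cell learns nothing
  W2 <- hebbian_update(W, c(0, 1, 0, 0), g, 0.2, p)
  expect_equal(W2[1, ], W[1, ])
  expect_false(all(W2[2, ] == W[2, ]))
  # fixed point w* = w_max (1 - g/g0)
  wstar <- pmin(pmax(p$w_max * (1 - g / p$g0), 0), p$w_max)
  Wfp <- matrix(wstar, 4, 4, byrow = TRUE)
  expect_equal(hebbian_update(Wfp, rep(1, 4), g, 0.2, p), Wfp,
               tolerance = 1e-12)
  # hand evaluation: eta 0.1, f 1, w 0, g 0 -> dw = 0.1 * 0.33 = 0.033
  W3 <- hebbian_update(matrix(0, 4, 4), rep(1, 4), rep(0, 4), 0.1, p)
  expect_equal(W3[1, 1], 0.033, tolerance = 1e-12)
})

test_that("clamped pair converges monotonically to the fixed point", {
  p <- ring_params(n_epg = 4, n_er = 4)
  g <- c(0.12, 0, 0, 0)
  f <- c(0.8, 0, 0, 0)
  wstar <- p$w_max * (1 - g[1] / p$g0)
  W <- matrix(0.33, 4, 4)
  err <- abs(W[1, 1] - wstar)
  for (i in 1:200) {
    W <- hebbian_update(W, f, g, 0.05, p)
    e2 <- abs(W[1, 1] - wstar)
    expect_lte(e2, err + 1e-12)
    err <- e2
  }
  expect_lt(err / wstar, 0.01)
})

test_that("presynaptic gating variant: silent ER input learns nothing and
           zero rate leaves weights unchanged", {
  p <- ring_params(n_epg = 4, n_er = 4, learning_gate = "presynaptic")
  W <- matrix(0.1, 4, 4)
  g <- c(0.3, 0, 0.2, 0)
  W2 <- presynaptic_update(W, rep(0.5, 4), g, 0.2, p)
  expect_equal(W2[, 2], W[, 2])
  expect_equal(W2[, 4], W[, 4])
  expect_false(all(W2[, 1] == W[, 1]))
  expect_equal(presynaptic_update(W, rep(0.5, 4), g, 0, p), W)
})

test_that("weight noise respects bounds and zero-sd is the identity", {
  p <- ring_params()
  W <- matrix(0.2, p$n_epg, p$n_er)
  expect_identical(add_weight_noise(W, p), W)
  p$weight_noise_sd <- 0.05
  set.seed(4)
  W2 <- add_weight_noise(W, p)
  expect_true(all(W2 >= 0 & W2 <= p$w_max))
  expect_false(all(W2 == W))
})

test_that("run_simulation without learning or noise leaves weights at their
           initial values and weights always stay in bounds", {
  cfg <- quick_cfg(seed = 3, duration_s = 30)
  tr <- gen_walking_trajectory(cfg)
  p <- ring_params(eta_gain = 0, seed = 3)
  s <- run_simulation(tr, p, stride_s = 10)
  expect_equal(s$W_final, s$W0, tolerance = 1e-14)
  p2 <- ring_params(seed = 3, weight_noise_sd = 5e-4)
  s2 <- run_simulation(tr, p2, stride_s = 10)
  expect_true(all(s2$W >= 0 & s2$W <= p2$w_max))
  expect_true(all(s2$f >= 0))
})

test_that("bump drifts monotonically under constant velocity", {
  p <- ring_params()
  tr <- const_rot_traj(45, 4)
  f0 <- visual_input(0, p)$g / p$g_max
  nT <- round(3.2 / p$dt)
  va <- p$v_gain * velocity_to_model(45, p)
  r <- flycompass:::run_ring_raw(rep(va, nT), rep(0, nT), rep(FALSE, nT),
                                 p, matrix(0, p$n_epg, p$n_er), f0,
                                 stride = 1L)
  ph <- flycompass:::unwrap_deg(r$phase)
  fit <- lm(ph ~ r$t)
  expect_gt(coef(fit)[2], 0)
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("divergent dynamics raise an informative error", {
  p <- ring_params(alpha = 5, D = 2, beta = 0)
  f0 <- visual_input(0, p)$g / p$g_max
  expect_error(
    flycompass:::run_ring_raw(rep(0, 2000), rep(0, 2000), rep(FALSE, 2000),
                              p, matrix(0, p$n_epg, p$n_er), f0),
    "diverged at step")
})
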