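#' ER population activity for a cue azimuth
#'
#' Ensemble ER activity is a von Mises profile over the evenly tiling
#' preferred azimuths, rescaled so its minimum is 0 and its maximum `g_max`.
#'
#' @param cue_azimuth cue azimuth in degrees.
#' @param params a [ring_params()].
#' @return list with `g` (length `n_er`, in `[0, g_max]`) and `prefs`
#'   (preferred azimuths in degrees).
#' @export
visual_input <- function(cue_azimuth, params) {
  prefs <- seq(0, 360 - 360 / params$n_er, by = 360 / params$n_er)
  vm <- exp(params$kappa * cos(deg2rad(cue_azimuth - prefs)))
  # scale so the peak sits at g_max, then zero the minimum: a flat profile
  # (kappa -> 0) carries no information and collapses to zero drive
  g <- (vm - min(vm)) * params$g_max / max(vm)
  list(g = g, prefs = prefs)
}

#' One Euler step of the ring dynamics (reference implementation)
#'
#' Scalar, loop-based update used as the oracle for the compiled simulation
#' core; both must agree to near machine precision.
#'
#' @param f rate vector (length `n_epg`).
#' @param W weight matrix (`n_epg x n_er`).
#' @param v rotational velocity in model units.
#' @param g ER activity vector.
#' @param noise per-neuron additive perturbation of `I_n` (default 0).
#' @param params a [ring_params()].
#' @return updated rate vector (non-negative).
#' @export
step_dynamics <- function(f, W, v, g, params, noise = 0) {
  n <- length(f)
  noise <- rep(noise, length.out = n)
  fn <- numeric(n)
  sumf <- sum(f)
  for (i in seq_len(n)) {
    ip <- if (i == n) 1L else i + 1L
    im <- if (i == 1) n else i - 1L
    I_i <- -sum(W[i, ] * g) + noise[i]
    br <- params$alpha * f[i] + params$D * (f[ip] + f[im]) -
      params$beta * sumf + 1 - v * (f[ip] - f[im]) / 2 + I_i
    br <- max(br, 0)
    fn[i] <- f[i] + params$dt / params$tau * (br - f[i])
  }
  fn <- pmax(fn, 0)
  if (any(!is.finite(fn))) stop("simulation diverged: non-finite rate")
  fn
}

#' Adaptive (speed-gated) learning rate
#'
#' `eta = eta_gain * |v|`, the "dopamine" gate: plasticity scales with
#' rotational speed, so no learning occurs while the fly holds its heading.
#'
#' @param v rotational velocity in model units (scalar or vector).
#' @param params a [ring_params()].
#' @return per-step learning rate(s).
#' @export
adaptive_eta <- function(v, params) params$eta_gain * abs(v)

#' Postsynaptically gated Hebbian weight update (reference implementation)
#'
#' `dW[n,m] = eta [f_n]_+ (w_max - W[n,m]) - eta [f_n]_+ w_max g_m / g0`,
#' clipped to `[0, w_max]`. The first term is non-associative potentiation at
#' synapses onto active EPG cells; the second is associative depression
#' requiring pre- and postsynaptic activity. Setting `dW = 0` gives the fixed
#' point `w* = w_max (1 - g/g0)` (clipped at 0 when `g > g0`).
#'
#' @param W weight matrix.
#' @param f postsynaptic EPG rates.
#' @param g presynaptic ER activities.
#' @param eta per-step learning rate.
#' @param params a [ring_params()].
#' @return updated weight matrix in `[0, w_max]`.
#' @export
hebbian_update <- function(W, f, g, eta, params) {
  fp <- pmax(f, 0)
  gate <- eta * fp  # one gate per postsynaptic (row) neuron
  dW <- gate * (params$w_max - W) - outer(gate, params$w_max * g / params$g0)
  pmin(pmax(W + dW, 0), params$w_max)
}

#' Presynaptically gated Hebbian variant (reconstructed)
#'
#' Mirrors the postsynaptic rule with the gate moved to the presynaptic ER
#' activity: `dW[n,m] = eta (g_m/g0) (w_max - W[n,m]) -
#' eta (g_m/g0) w_max [f_n]_+ / f_ref`. This is a reconstruction: it
#' preserves the rule's defining property (no learning at silent ER inputs)
#' and its fixed-point structure rather than any particular canonical form.
#'
#' @inheritParams hebbian_update
#' @param f_ref rate normalization for the depression term.
#' @return updated weight matrix in `[0, w_max]`.
#' @export
presynaptic_update <- function(W, f, g, eta, params, f_ref = 1) {
  gate <- eta * g / params$g0
  fp <- pmax(f, 0)
  dW <- sweep(params$w_max - W, 2, gate, `*`) -
    outer(fp / f_ref * params$w_max, gate)
  pmin(pmax(W + dW, 0), params$w_max)
}

#' Add Gaussian noise to the weight matrix
#'
#' Elementwise `N(0, sd^2)` perturbation followed by clipping to
#' `[0, w_max]`; models ongoing synaptic turnover that learning must combat.
#'
#' @param W weight matrix.
#' @param params a [ring_params()] (uses `weight_noise_sd`, `w_max`).
#' @return perturbed, clipped weight matrix.
#' @export
add_weight_noise <- function(W, params) {
  if (params$weight_noise_sd == 0) return(W)
  W2 <- W + matrix(rnorm(length(W), sd = params$weight_noise_sd),
                   nrow(W), ncol(W))
  pmin(pmax(W2, 0), params$w_max)
}

#' Simulate the plastic ring attractor on a walking trajectory
#'
#' Resamples the trajectory's rotational velocity to the model's time grid,
#' drives the virtual cue azimuth with the accumulated rotation (closed
#' loop), and integrates rate dynamics, visual noise, Hebbian learning
#' (adaptive or fixed rate) and optional weight noise at every step. Weights
#' are initialized uniformly on `[0, w_max]` from `params$seed`.
#'
#' @param traj an `fc_trajectory`, or a list with fields `t` and
#'   `rot_velocity` on a uniform grid.
#' @param params a [ring_params()].
#' @param duration_s optional truncation of the trajectory.
#' @param stride_s snapshot interval in seconds of simulated time.
#' @param W0,f0 optional initial weights / rates (defaults: uniform random
#'   weights, zero rates).
#' @param dark if `TRUE` the visual input (and learning) is off: the bump is
#'   sustained by the attractor alone.
#' @return list of class `fc_sim`: `t` (snapshot times), `W`
#'   (`n_epg x n_er x n_snap`), `f` (`n_epg x n_snap`), `phase` (bump PVA
#'   phase per snapshot, deg), `eta`, `W_final`, `f_final`, `eta_mean`
#'   (mean per-step rate actually applied), `params`.
#' @export
run_simulation <- function(traj, params, duration_s = NULL, stride_s = 10,
                           W0 = NULL, f0 = NULL, dark = FALSE) {
  dt <- params$dt
  t_end <- if (is.null(duration_s)) max(traj$t) else min(duration_s, max(traj$t))
  tg <- seq(dt, t_end, by = dt)
  v_deg <- approx(traj$t, traj$rot_velocity, xout = tg, rule = 2)$y
  v_model <- velocity_to_model(v_deg, params)
  v_advect <- params$v_gain * v_model
  # virtual cue azimuth follows the accumulated rotation (closed loop)
  cue <- wrap360(cumsum(v_deg) * dt)
  eta <- switch(params$eta_mode,
    adaptive = adaptive_eta(v_model, params),
    fixed = {
      e <- params$eta_fixed
      if (is.na(e)) e <- mean(adaptive_eta(v_model, params))
      rep(e, length(tg))
    })
  if (dark) eta[] <- 0
  stride <- max(1L, round(stride_s / dt))

  with_seed(params$seed, {
    if (is.null(W0)) {
      W0 <- matrix(runif(params$n_epg * params$n_er, 0, params$w_max),
                   params$n_epg, params$n_er)
    }
    if (is.null(f0)) f0 <- rep(0, params$n_epg)
    noise_window <- max(1L, round(params$noise_smooth_s / dt))
    res <- simulate_ring_cpp(v_advect, cue, rep(!dark, length(tg)), eta,
                             W0, f0,
                             params$tau, params$alpha, params$D, params$beta,
                             params$w_max, params$g_max, params$g0,
                             params$kappa, dt,
                             params$noise_hi, noise_window,
                             params$weight_noise_sd,
                             params$learning_gate == "presynaptic", 1,
                             stride)
    res$eta_mean <- mean(eta)
    res$params <- params
    res$W0 <- W0
    class(res) <- "fc_sim"
    res
  })
}

# low-level driver used by calibration and tests: explicit velocity/cue
# series in model units on the dt grid, no learning unless eta given
run_ring_raw <- function(v_model, cue_deg, cue_on, params, W0, f0,
                         eta = rep(0, length(v_model)), stride = 1L,
                         noise_hi = 0) {
  noise_window <- max(1L, round(params$noise_smooth_s / params$dt))
  simulate_ring_cpp(v_model, cue_deg, cue_on, eta, W0, f0,
                    params$tau, params$alpha, params$D, params$beta,
                    params$w_max, params$g_max, params$g0, params$kappa,
                    params$dt, noise_hi, noise_window,
                    params$weight_noise_sd,
                    params$learning_gate == "presynaptic", 1, stride)
}

#' Check (or search for) attractor-forming dynamics parameters
#'
#' The rate equation does not by itself pin down `alpha`, `D` and `beta`,
#' so the package calibrates them: a parameter set is
#' accepted when (i) with no visual input and `v = 0`, a bump seeded at one
#' azimuth persists with bounded drift and does not spread to uniformity, and
#' (ii) with constant `v`, the bump phase advances linearly (R-squared of
#' unwrapped phase vs time above 0.95). `calibrate_ring()` sweeps a small
#' grid and returns the first passing set; `check_attractor()` evaluates one
#' set.
#'
#' @param params a [ring_params()].
#' @param test_s simulated seconds for each probe.
#' @param v_test probe velocity in model units.
#' @return `check_attractor()`: list with `single_bump`, `drift_deg`,
#'   `track_r2`, `ok`. `calibrate_ring()`: a passing [ring_params()].
#' @export
check_attractor <- function(params, test_s = 30,
                            v_probe_deg = c(20, 40, 60, 80)) {
  nT <- round(test_s / params$dt)
  # seed a bump, then run in darkness at v = 0
  f0 <- visual_input(0, params)$g / params$g_max
  W0 <- matrix(0, params$n_epg, params$n_er)
  still <- run_ring_raw(rep(0, nT), rep(0, nT), rep(FALSE, nT), params,
                        W0, f0, stride = max(1L, round(0.5 / params$dt)))
  fT <- still$f_final
  pk <- max(fT)
  single_bump <- is.finite(pk) && pk > 1e-3 && pk < 50 &&
    (min(fT) / pk) < 0.25 && sum(fT > pk / 2) <= ceiling(params$n_epg / 2)
  drift <- abs(circ_dist_deg(tail(still$phase, 1), 0))
  # constant-velocity probes from the settled bump: displacement must be
  # proportional to v * T over the behavioural velocity range
  probe_s <- 5
  nP <- round(probe_s / params$dt)
  speed <- vapply(v_probe_deg, function(vd) {
    va <- params$v_gain * velocity_to_model(vd, params)
    mv <- run_ring_raw(rep(va, nP), rep(0, nP), rep(FALSE, nP), params,
                       W0, still$f_final, stride = 1L)
    ph <- unwrap_deg(mv$phase)
    unname(coef(lm(ph ~ mv$t))[2])
  }, numeric(1))
  fit <- lm(disp ~ 0 + vt, data = data.frame(disp = speed * probe_s,
                                             vt = v_probe_deg * probe_s))
  track_r2 <- summary(fit)$r.squared
  gain <- unname(coef(fit)[1])
  list(single_bump = single_bump, drift_deg = drift, track_r2 = track_r2,
       gain = gain,
       ok = single_bump && drift < 45 && track_r2 > 0.95 && gain > 0.1)
}

#' @rdname check_attractor
#' @param alpha_grid,D_grid,beta_grid candidate values swept in order.
#' @export
calibrate_ring <- function(params = ring_params(),
                           alpha_grid = c(0.8, 1.0, 0.6),
                           D_grid = c(0.2, 0.3, 0.4),
                           beta_grid = c(0.3, 0.5, 0.2),
                           test_s = 30) {
  for (a in alpha_grid) for (d in D_grid) for (b in beta_grid) {
    p <- params
    p$alpha <- a; p$D <- d; p$beta <- b
    chk <- check_attractor(p, test_s = test_s)
    if (chk$ok) {
      # one refinement round: rescale v_gain for a unit heading-to-bump gain
      p$v_gain <- p$v_gain / chk$gain
      chk2 <- check_attractor(p, test_s = test_s)
      if (chk2$ok) return(p)
    }
  }
  stop("no parameter set in the sweep produced a tracking attractor")
}
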