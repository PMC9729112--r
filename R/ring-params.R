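#' Parameters of the ring-attractor learning model
#'
#' The compass (EPG) population is a 1-D ring of `n_epg` rate units obeying
#' `tau df_n/dt = -f_n + [alpha f_n + D (f_{n+1} + f_{n-1}) - beta sum(f)
#' + 1 - v (f_{n+1} - f_{n-1})/2 + I_n]_+`, with visual ring-neuron (ER)
#' input `I_n = -sum_m W[n,m] g_m + noise` and a Hebbian rule at the ER->EPG
#' synapses whose rate `eta` is either fixed or scales with rotational speed
#' (`eta = eta_gain * |v|`, the adaptive "dopamine" gate).
#'
#' `tau`, `w_max`, `g0`, `g_max`, `kappa`, `dt`, the weight range, the
#' visual-noise model (uniform on `[0, 0.5 g_max]`, box-car averaged over
#' 80 ms) and the learning rule are the standard constants of this circuit
#' model; `alpha`,
#' `D`, `beta` and the population sizes are set by the shipped
#' [calibrate_ring()] sweep (a unique stable bump at `v = 0` that tracks a
#' constant-velocity input).
#'
#' @param n_epg,n_er population sizes (preferred azimuths evenly tile 360
#'   degrees).
#' @param tau rate decay time constant, s.
#' @param alpha self-excitation strength.
#' @param D nearest-neighbour excitation strength.
#' @param beta global inhibition strength.
#' @param w_max upper weight bound (weights live in `[0, w_max]`).
#' @param g0 depression scale of the Hebbian rule.
#' @param g_max upper bound of ER activity.
#' @param kappa von Mises concentration of the ER activity profile.
#' @param dt integration step, s.
#' @param v_gain gain applied to the velocity before it enters the advection
#'   term. The advection input sets the bump's drift rate at roughly
#'   `v_advect / tau`, so `v_gain` near `tau` makes the bump integrate the
#'   fly's rotation veridically; [calibrate_ring()] refines it so that bump
#'   angular speed matches heading speed 1:1 over the behavioural range.
#'   The learning rate always uses the unscaled model-unit velocity.
#' @param eta_mode `"adaptive"` (`eta = eta_gain |v|`) or `"fixed"`.
#' @param eta_fixed fixed per-step learning rate; `NA` means "match the mean
#'   adaptive rate of the same trajectory" (equal total learning).
#' @param eta_gain adaptive gain per unit of model velocity: the per-step
#'   learning rate is `eta_gain * |v|` (proportional to rotational speed,
#'   the dopamine gate). The default puts the network in the slow-learning
#'   regime — weight equilibration over minutes, long compared with a single
#'   heading-fixation bout but short compared with a training session —
#'   which is the regime in which a speed-gated learning rate protects the
#'   map from over-learning a fixated view (see the package vignette).
#' @param noise_hi upper bound of the uniform visual noise (default
#'   `0.5 * g_max`).
#' @param noise_smooth_s box-car window for the visual noise, s.
#' @param weight_noise_sd per-step SD of Gaussian weight noise (0 = off).
#' @param learning_gate `"postsynaptic"` (the default rule) or
#'   `"presynaptic"` (reconstructed variant gated by ER activity).
#' @param seed integer seed for weight initialization and noise.
#' @return a `ring_params` list.
#' @export
ring_params <- function(n_epg = 32, n_er = 32,
                        tau = 0.050,
                        alpha = 0.8, D = 0.2, beta = 0.3,
                        w_max = 0.33, g0 = 0.33, g_max = 0.35,
                        kappa = 15, dt = 0.0161, v_gain = 0.0617,
                        eta_mode = c("adaptive", "fixed"),
                        eta_fixed = NA_real_, eta_gain = 5e-5,
                        noise_hi = 0.5 * g_max, noise_smooth_s = 0.080,
                        weight_noise_sd = 0,
                        learning_gate = c("postsynaptic", "presynaptic"),
                        seed = 1L) {
  eta_mode <- match.arg(eta_mode)
  learning_gate <- match.arg(learning_gate)
  stopifnot(dt > 0, dt <= tau, w_max > 0, g0 > 0, g_max > 0, kappa > 0,
            n_epg >= 4, n_er >= 4, eta_gain >= 0, weight_noise_sd >= 0)
  structure(list(n_epg = as.integer(n_epg), n_er = as.integer(n_er),
                 tau = tau, alpha = alpha, D = D, beta = beta,
                 w_max = w_max, g0 = g0, g_max = g_max, kappa = kappa,
                 dt = dt, v_gain = v_gain,
                 eta_mode = eta_mode, eta_fixed = eta_fixed,
                 eta_gain = eta_gain, noise_hi = noise_hi,
                 noise_smooth_s = noise_smooth_s,
                 weight_noise_sd = weight_noise_sd,
                 learning_gate = learning_gate, seed = as.integer(seed)),
            class = "ring_params")
}

#' Convert rotational velocity from deg/s to model units
#'
#' The advection term of the rate equation is a discrete spatial derivative,
#' so `v` is measured in neuron indices per second:
#' `v_model = v_deg * n_epg / 360`.
#'
#' @param v_deg velocity in deg/s.
#' @param params a [ring_params()].
#' @return velocity in model units.
#' @export
velocity_to_model <- function(v_deg, params) v_deg * params$n_epg / 360
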