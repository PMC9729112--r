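# Run expr with a locally seeded RNG, restoring the caller's RNG state, so
# generators are pure functions of (cfg, seed).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# unit-variance Ornstein-Uhlenbeck process on a uniform grid (exact update)
ou_process <- function(n, dt, tau_ou = 0.5) {
  a <- exp(-dt / tau_ou)
  innov_sd <- sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- rnorm(1)
  eps <- rnorm(n - 1)
  for (k in 2:n) x[k] <- a * x[k - 1] + innov_sd * eps[k - 1]
  x
}

#' Generate a synthetic walking-fly trajectory
#'
#' A two-state (rest/move) semi-Markov process with exponential epoch dwell
#' times; moving epochs are subdivided into heading-fixation epochs
#' (near-zero rotation, steady forward walking) and turning epochs where
#' rotational velocity follows an Ornstein-Uhlenbeck process with stationary
#' SD `rot_speed_scale`. Heading is the wrapped cumulative integral of
#' rotational velocity. The latent epoch state is returned as ground truth.
#'
#' @param cfg a [synth_config()].
#' @return data frame of class `fc_trajectory` with columns `t` (s),
#'   `rot_velocity` (deg/s, positive = rightward), `fwd_velocity` (mm/s,
#'   non-negative), `heading` (deg in `[0, 360)`) and `state`
#'   (`"rest"`, `"fixation"`, `"turning"`).
#' @export
gen_walking_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  dt <- 1 / cfg$sample_rate_hz
  n <- round(cfg$duration_s * cfg$sample_rate_hz)
  if (n < 10) stop("invalid config: duration shorter than 10 samples")

  with_seed(cfg$seed, {
    # epoch sequence: iid type draws with exponential dwells. Flies hold a
    # heading for tens of seconds at a time, so fixation (and rest) bouts are
    # long; sampling probabilities are scaled by 1/dwell so the expected time
    # fractions still equal the configured fractions.
    dwell_s <- c(rest = 10, fixation = 25, turning = 8)
    frac <- c(rest = cfg$rest_fraction, fixation = cfg$fixation_fraction,
              turning = max(0, 1 - cfg$rest_fraction - cfg$fixation_fraction))
    probs <- frac / dwell_s
    state <- character(0)
    while (length(state) < n) {
      type <- sample(names(probs), 1, prob = probs)
      dwell <- max(1, rexp(1, rate = 1 / dwell_s[[type]]))
      state <- c(state, rep(type, max(1L, round(dwell / dt))))
    }
    state <- state[seq_len(n)]

    rot_sd <- c(rest = 0.05, fixation = 0.08, turning = 1)[state] *
      cfg$rot_speed_scale
    rot <- if (cfg$rot_speed_scale > 0) ou_process(n, dt) * rot_sd else numeric(n)

    moving <- state != "rest"
    fwd_mu <- ifelse(moving, cfg$fwd_speed_scale, 0)
    fwd_sd <- ifelse(moving, cfg$fwd_speed_scale / 4, 0.3)
    fwd <- pmax(0, fwd_mu + ou_process(n, dt) * fwd_sd)

    heading <- wrap360(cumsum(rot) * dt)

    structure(data.frame(t = (seq_len(n) - 1) * dt, rot_velocity = rot,
                         fwd_velocity = fwd, heading = heading,
                         state = state),
              class = c("fc_trajectory", "data.frame"),
              sample_rate_hz = cfg$sample_rate_hz, config = cfg)
  })
}
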