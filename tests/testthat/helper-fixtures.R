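# shared fixtures, all generated in code

# von Mises sampler (Best & Fisher rejection method), degrees
rvonmises <- function(n, mu_deg = 0, kappa = 1) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  th <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      th[i] <- (sign(u[3] - 0.5) * acos(f) + mu_deg * pi / 180) %% (2 * pi)
      i <- i + 1
    }
  }
  th * 180 / pi
}

# trajectory with a prescribed constant rotational velocity, bypassing the
# stochastic generator
const_rot_traj <- function(rot_deg_s, duration_s, rate_hz = 60) {
  t <- seq(0, duration_s, by = 1 / rate_hz)
  t <- t[t < duration_s]
  data.frame(t = t, rot_velocity = rep(rot_deg_s, length(t)),
             fwd_velocity = rep(0, length(t)),
             heading = wrap360(cumsum(rep(rot_deg_s, length(t))) / rate_hz))
}

# fast default config for tests that only need a short series
quick_cfg <- function(seed = 1, duration_s = 60, ...) {
  synth_config(seed = seed, duration_s = duration_s, ...)
}
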