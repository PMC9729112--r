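#include <Rcpp.h>
using namespace Rcpp;

// Euler integration of the 1-D ring attractor with plastic visual input.
//
// Rate dynamics per step (circular indexing, [x]_+ rectification):
//   tau df_n/dt = -f_n + [ alpha f_n + D (f_{n+1} + f_{n-1}) - beta sum_m f_m
//                          + 1 - v (f_{n+1} - f_{n-1}) / 2 + I_n ]_+
// with I_n = -(W g)_n + noise_n, g a von Mises profile over ER preferred
// azimuths rescaled to [0, g_max], and the Hebbian update
//   dW_{n,m} = eta [f_n]_+ (w_max - W_{n,m}) - eta [f_n]_+ w_max g_m / g0
// (postsynaptic gating; a reconstructed presynaptically gated variant swaps
// the [f_n]_+ gate for g_m/g0 and gates the depression term by the
// conjunction). Weights are clipped to [0, w_max] after every update.
//
// Noise on I_n: per-EPG-neuron uniform draws on [0, noise_hi], box-car
// averaged over noise_window steps. All randomness uses R's RNG so that
// set.seed() at the R level makes runs reproducible.

static inline double wrap360(double x) {
  double y = x - 360.0 * std::floor(x / 360.0);
  if (y >= 360.0) y -= 360.0;
  return y;
}

// [[Rcpp::export]]
List simulate_ring_cpp(NumericVector v_model,
                       NumericVector cue_deg,
                       LogicalVector cue_on,
                       NumericVector eta,
                       NumericMatrix W0,
                       NumericVector f0,
                       double tau, double alpha, double D, double beta,
                       double w_max, double g_max, double g0, double kappa,
                       double dt,
                       double noise_hi, int noise_window,
                       double weight_noise_sd,
                       bool presynaptic, double f_ref,
                       int stride) {
  const int T = v_model.size();
  const int n_epg = f0.size();
  const int n_er = W0.ncol();
  if (W0.nrow() != n_epg) stop("W0 must be n_epg x n_er");
  if (cue_deg.size() != T || eta.size() != T || cue_on.size() != T)
    stop("v_model, cue_deg, cue_on and eta must have equal length");
  if (stride < 1) stop("stride must be >= 1");

  std::vector<double> f(f0.begin(), f0.end());
  std::vector<double> W(n_epg * (size_t)n_er);
  for (int n = 0; n < n_epg; ++n)
    for (int m = 0; m < n_er; ++m)
      W[n + (size_t)n_epg * m] = W0(n, m);

  // ER preferred azimuths and EPG angular positions evenly tile [0, 360)
  std::vector<double> er_pref_rad(n_er), epg_cos(n_epg), epg_sin(n_epg);
  for (int m = 0; m < n_er; ++m)
    er_pref_rad[m] = 2.0 * M_PI * m / n_er;
  for (int n = 0; n < n_epg; ++n) {
    epg_cos[n] = std::cos(2.0 * M_PI * n / n_epg);
    epg_sin[n] = std::sin(2.0 * M_PI * n / n_epg);
  }

  // ring buffer for box-car averaged uniform noise, one channel per EPG cell
  const bool use_noise = noise_hi > 0.0 && noise_window > 0;
  std::vector<double> nbuf;
  std::vector<double> nsum(n_epg, 0.0);
  int nhead = 0;
  if (use_noise) nbuf.assign((size_t)n_epg * noise_window, 0.0);

  const int n_snap = T / stride;
  NumericVector W_snap((size_t)n_snap * n_epg * n_er);
  W_snap.attr("dim") = IntegerVector::create(n_epg, n_er, n_snap);
  NumericMatrix f_snap(n_epg, n_snap);
  NumericVector phase_snap(n_snap), t_snap(n_snap), eta_snap(n_snap);

  std::vector<double> g(n_er), b(n_epg), noise(n_epg, 0.0);
  RNGScope scope;
  int isnap = 0;

  for (int k = 0; k < T; ++k) {
    // visual drive: von Mises over azimuth, min set to 0, max to g_max
    if (cue_on[k]) {
      double az = cue_deg[k] * M_PI / 180.0;
      double gmin = R_PosInf, gmax_raw = R_NegInf;
      for (int m = 0; m < n_er; ++m) {
        double val = std::exp(kappa * std::cos(az - er_pref_rad[m]));
        g[m] = val;
        if (val < gmin) gmin = val;
        if (val > gmax_raw) gmax_raw = val;
      }
      // peak scaled to g_max, minimum subtracted to zero
      for (int m = 0; m < n_er; ++m) g[m] = (g[m] - gmin) * g_max / gmax_raw;
    } else {
      std::fill(g.begin(), g.end(), 0.0);
    }

    if (use_noise) {
      for (int n = 0; n < n_epg; ++n) {
        double draw = unif_rand() * noise_hi;
        size_t idx = (size_t)n * noise_window + nhead;
        nsum[n] += draw - nbuf[idx];
        nbuf[idx] = draw;
        noise[n] = nsum[n] / noise_window;
      }
      nhead = (nhead + 1) % noise_window;
    }

    // rate update (forward Euler)
    double sumf = 0.0;
    for (int n = 0; n < n_epg; ++n) sumf += f[n];
    const double v = v_model[k];
    for (int n = 0; n < n_epg; ++n) {
      const int np = (n + 1) % n_epg, nm = (n - 1 + n_epg) % n_epg;
      double I_n = 0.0;
      if (cue_on[k]) {
        for (int m = 0; m < n_er; ++m) I_n -= W[n + (size_t)n_epg * m] * g[m];
      }
      I_n += noise[n];
      double br = alpha * f[n] + D * (f[np] + f[nm]) - beta * sumf + 1.0
                  - v * (f[np] - f[nm]) / 2.0 + I_n;
      if (br < 0) br = 0;
      b[n] = f[n] + dt / tau * (br - f[n]);
    }
    for (int n = 0; n < n_epg; ++n) {
      double fn = b[n];
      if (fn < 0) fn = 0;
      if (!std::isfinite(fn) || fn > 1e8) {
        stop("simulation diverged at step %d (rate %g)", k + 1, b[n]);
      }
      f[n] = fn;
    }

    // Hebbian update
    const double et = eta[k];
    if (et > 0.0 && cue_on[k]) {
      if (!presynaptic) {
        for (int m = 0; m < n_er; ++m) {
          const double dep = w_max * g[m] / g0;
          const size_t off = (size_t)n_epg * m;
          for (int n = 0; n < n_epg; ++n) {
            const double gate = et * f[n];
            if (gate <= 0) continue;
            double w = W[n + off];
            w += gate * (w_max - w) - gate * dep;
            if (w < 0) w = 0; else if (w > w_max) w = w_max;
            W[n + off] = w;
          }
        }
      } else {
        for (int m = 0; m < n_er; ++m) {
          const double pregate = et * g[m] / g0;
          if (pregate <= 0) continue;
          const size_t off = (size_t)n_epg * m;
          for (int n = 0; n < n_epg; ++n) {
            double w = W[n + off];
            w += pregate * (w_max - w) - pregate * w_max * f[n] / f_ref;
            if (w < 0) w = 0; else if (w > w_max) w = w_max;
            W[n + off] = w;
          }
        }
      }
    }

    if (weight_noise_sd > 0.0) {
      for (size_t i = 0; i < W.size(); ++i) {
        double w = W[i] + norm_rand() * weight_noise_sd;
        if (w < 0) w = 0; else if (w > w_max) w = w_max;
        W[i] = w;
      }
    }

    // snapshot
    if ((k + 1) % stride == 0 && isnap < n_snap) {
      for (int m = 0; m < n_er; ++m)
        for (int n = 0; n < n_epg; ++n)
          W_snap[(size_t)isnap * n_epg * n_er + n + (size_t)n_epg * m] =
            W[n + (size_t)n_epg * m];
      double cs = 0.0, sn = 0.0;
      for (int n = 0; n < n_epg; ++n) {
        f_snap(n, isnap) = f[n];
        cs += f[n] * epg_cos[n];
        sn += f[n] * epg_sin[n];
      }
      phase_snap[isnap] = wrap360(std::atan2(sn, cs) * 180.0 / M_PI);
      t_snap[isnap] = (k + 1) * dt;
      eta_snap[isnap] = et;
      ++isnap;
    }
  }

  NumericMatrix W_final(n_epg, n_er);
  for (int m = 0; m < n_er; ++m)
    for (int n = 0; n < n_epg; ++n)
      W_final(n, m) = W[n + (size_t)n_epg * m];
  NumericVector f_final(f.begin(), f.end());

  return List::create(_["W"] = W_snap, _["f"] = f_snap,
                      _["phase"] = phase_snap, _["t"] = t_snap,
                      _["eta"] = eta_snap,
                      _["W_final"] = W_final, _["f_final"] = f_final);
}
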