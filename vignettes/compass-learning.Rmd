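---
title: "Speed-gated plasticity in the fly head-direction circuit: model and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speed-gated plasticity in the fly head-direction circuit: model and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flycompass)
```

# The scientific problem

The *Drosophila* head-direction system maintains a single localized "bump"
of activity in a ring of compass (EPG) neurons. Visual ring (ER) neurons
carry the azimuth of landmarks and synapse onto the compass ring through
plastic, effectively inhibitory connections; Hebbian plasticity at these
synapses is what lets a fly register an arbitrary visual scene to its
internal heading. Plasticity, however, is a liability when the fly stands
still or fixates one heading for a long time: learning keeps running while
the gaze samples a single view, and the visual-to-heading map gets
over-written by that one association. A dopaminergic "when-to-learn" signal
— ExR2 neurons whose activity scales with rotational speed — solves this by
gating the learning rate: plasticity runs only while the head direction is
actually changing.

`flycompass` implements this circuit model and the analysis toolchain
around it: synthetic walking-fly behaviour and imaging/electrophysiology
surrogates, the ring-attractor simulation with adaptive or fixed learning
rate, weight-map regularity metrics, the calcium-bump pipeline
(population-vector average, offset, amplitude), a Kraskov k-nearest-
neighbour mutual-information estimator, circular tuning statistics, spike
detection, and locomotor regression models.

# The ring model

The compass population is a 1-D ring of `n_epg` rate units:

$$\tau \frac{df_n}{dt} = -f_n + \Big[\alpha f_n + D(f_{n+1}+f_{n-1})
  - \beta \textstyle\sum_m f_m + 1 - v\,(f_{n+1}-f_{n-1})/2 + I_n\Big]_+$$

with decay constant $\tau = 50$ ms, circular indexing, rectification
$[\cdot]_+$, and visual input $I_n = -\sum_m W_{n,m}\, g_m + \xi_n$. ER
activity $g$ is a von Mises profile ($\kappa = 15$) over evenly tiling
preferred azimuths, scaled so its peak is $g_{max} = 0.35$ and its minimum
0. Visual noise $\xi_n$ is uniform on $[0, 0.5\,g_{max}]$ per neuron,
box-car averaged over 80 ms. Weights evolve by a postsynaptically gated
Hebbian rule

$$\Delta W_{n,m} = \eta\,[f_n]_+ (w_{max} - W_{n,m})
  - \eta\,[f_n]_+\, w_{max}\, g_m / g_0$$

with $w_{max} = g_0 = 0.33$ and weights clipped to $[0, w_{max}]$. The
first term is non-associative potentiation at active compass cells, the
second associative depression; setting $\Delta W = 0$ gives the fixed point
$w^\ast = w_{max}(1 - g/g_0)$, so a trained row is saturated everywhere
except for a "notch" at its associated cue azimuth. Integration is forward
Euler at $dt = 16.1$ ms. A reconstructed presynaptically gated variant
(gate $g_m/g_0$, depression by the pre/post conjunction) is available
behind `learning_gate = "presynaptic"`.

## Calibrated parameters

Three dynamics constants ($\alpha$, self-excitation; $D$, neighbour
excitation; $\beta$, global inhibition) and the population sizes are not
fixed by the rate equation itself, so the package ships a calibration,
`calibrate_ring()`, whose acceptance conditions are: (i) with no visual
input and $v = 0$, a seeded bump persists without spreading; (ii) with
constant $v$, the bump's angular displacement is linear in $v\,t$
($R^2 > 0.95$). The shipped defaults are $\alpha = 0.8$, $D = 0.2$,
$\beta = 0.3$, $n_{epg} = n_{er} = 32$. Deeper attractors (higher bump
rates) resist the visual noise; much shallower ones let noise teleport the
bump and no coherent map can form.

Two further scalings are calibrated rather than assumed, because their
unit conventions are not fixed by the equations above:

* **Advection gain.** The term $v(f_{n+1}-f_{n-1})/2$ drives bump drift at
  a rate close to $v/\tau$, not $v$: feeding raw velocities (neuron
  indices/s) makes the bump rotate an order of magnitude faster than the
  fly. `v_gain` (default 0.0617, refined by `calibrate_ring()`) scales the
  advection input so one degree of fly rotation moves the bump one degree.
* **Learning-rate gain.** The adaptive rate is $\eta = \eta_{gain}\,|v|$,
  proportional to rotational speed as the dopamine signal demands. The
  magnitude of $\eta_{gain}$ sets the weight-equilibration time, and the
  model only reproduces the adaptive-vs-fixed contrast in the
  *slow-learning regime*: equilibration must be long compared with a single
  heading-fixation bout (tens of seconds) and short compared with a
  training session (thousands of seconds). In that regime the weights
  time-average the behaviour, so a fixed rate lets long fixations dominate
  the average (over-learning one view) while the speed-gated rate discounts
  them. With fast learning the most recent movement always re-writes the
  map and the contrast vanishes; with per-step rates above $2/f$ the update
  is numerically unstable outright. The default $\eta_{gain} = 5\times
  10^{-5}$ per (neuron-index/s) puts equilibration at a few minutes.

Matched-total-learning controls set `eta_mode = "fixed"` with
`eta_fixed = NA`, which uses the mean adaptive rate of the same trajectory.

## Map regularity

A learned map is scored by the circular correlation between two angle
vectors: the PVA of each ER neuron's output-weight column (over compass
positions) and the PVA of each compass neuron's input-weight row (over ER
azimuths), paired by azimuth. Because both vectors tile the full circle,
the mean-centred circular correlation coefficient is degenerate here (the
circular mean of a near-uniform angle set is determined by noise); the
package therefore uses the pairwise T-linear form

$$\rho = \frac{\sum_{i<j} \sin(a_i-a_j)\sin(b_i-b_j)}
  {\sqrt{\sum_{i<j}\sin^2(a_i-a_j)\,\sum_{i<j}\sin^2(b_i-b_j)}},$$

which is rotation invariant, 1 for a perfectly ordered map, $-1$ for a
mirrored one, and near 0 for random weights. Inhibitory maps (notches
instead of peaks) shift every PVA by a common 180 degrees and leave $\rho$
unchanged.

# The synthetic-data generators

All analyses run on synthetic data with known ground truth; every
generator is a pure function of its configuration and seed, and returns
its latent truth alongside the observable.

* **Walking trajectory** (`gen_walking_trajectory`): a semi-Markov
  rest/fixation/turning process at 60 Hz. Dwell times are exponential with
  means 10 s (rest), 25 s (fixation) and 8 s (turning) — flies hold
  headings for tens of seconds, and long fixations are precisely the
  condition that distinguishes the two learning rules. Sampling
  probabilities are scaled by 1/dwell so realized time fractions match the
  configured `rest_fraction`/`fixation_fraction`. Rotational velocity is an
  Ornstein-Uhlenbeck process whose stationary SD is `rot_speed_scale`
  during turning and a few percent of it during rest and fixation; forward
  velocity is non-negative and elevated while moving. No published summary
  statistics of the flies' walking exist, so these dwell times and scales
  are plausible choices, fixed once.
* **Cue streams**: closed loop (cue yoked to heading) and open loop
  (constant ~18 deg/s ramp with annotated 360-degree cycles). Azimuth 0
  means "cue in front"; samples with the cue at 150-210 degrees are hidden
  behind the fly and excluded from offset and MI analyses.
* **ExR2-like activity** (`gen_exr2_dff`): dF/F linear in rotational speed
  with a 300 ms lag and Gaussian noise.
* **Eight-wedge bump fluorescence** (`gen_epg_wedges`): a von Mises bump
  whose phase follows the reference angle with fidelity `coupling`
  (1 = locked; 0 = an independent circular random walk, 30 deg/volume by
  default); amplitude is `1 + amp_speed_gain * |rot speed|`; downsampled to
  the 6-9 Hz volume rate with additive noise. `coupling2`/`step_at_s`
  switch the coupling mid-session, emulating an abrupt gain of cue control.
* **Voltage traces** (`gen_voltage_trace`): cosine tuning around a
  preferred azimuth on a -55 mV baseline, biexponential ~3 ms spike
  templates at a tuning-modulated rate, optional abrupt remapping of the
  preferred azimuth at a chosen cycle.

What the generators do *not* emulate: photon shot noise and bleaching,
motion artefacts, the LED panel geometry, heterogeneous wedge gains,
inhibitory-event contamination of patch recordings, or any between-fly
variability structure. Passing tests therefore demonstrate that the
analysis code recovers what it claims from data with the assumed
statistical structure, not that it is robust to every artefact of real
recordings.

# Analysis conventions and numerical choices

* Angles are degrees in $[0, 360)$; differences in $(-180, 180]$; positive
  rotation is rightward.
* dF/F uses the 5th percentile of the raw trace as baseline. "Gaussian
  kernel X in width" is read as full width $X$ with $\sigma = X/4$,
  truncated at $\pm 2\sigma$, reflection padding; tests that depend on this
  use relative assertions. Speed alignment downsamples to the volume grid,
  smooths 10 times with a 60 ms kernel, and shifts the speed series two
  volumes (~300 ms) back in time.
* The KSG estimator (algorithm 1, $k = 3$, max norm, tiny tie-breaking
  jitter) reports nats. Circular variables are embedded as $(\cos, \sin)$
  pairs, which makes estimates invariant to rigid rotations; a raw-angle
  path would put a spurious discontinuity at the wrap. On strongly
  autocorrelated series (a drifting bump within a single 20 s cue cycle)
  the estimator keeps a positive bias even at zero coupling — windowed
  *changes* in MI, which the analyses report, are robust to this, and the
  tests assert contrasts rather than absolute zeros.
* Undefined PVAs (symmetric activity) propagate as missing values and are
  excluded from offset and MI statistics. Equal-count binning breaks ties
  by stable sort order; per-bin counts differ by at most 1.
* The Watson-Williams test includes the standard $1 + 3/(8\hat\kappa)$
  correction and flags low-concentration samples; Bonferroni-corrected
  p-values are reported uncapped, following the reporting style of
  single-cell screens. The Rayleigh p-value uses the standard series
  approximation.
* Spike detection low-pass filters (Butterworth, order 2, default 500 Hz),
  differentiates, thresholds, and applies a 2.5 ms width gate — measured at
  the base (10% of peak) of the filtered deflection, i.e. the full spike
  footprint — and a 2 ms refractory gate. The cutoff and threshold defaults
  were chosen on the synthetic templates, standing in for the per-cell
  empirical choice such recordings require.
* The weight-noise replicate uses per-step Gaussian SD $5\times10^{-4}$,
  a free parameter here: large enough that an unmaintained map
  degrades within ~1000 s, small enough that gated learning can repair it.

# Problem sizes

The shipped checks use the model's native temporal scales with modest
replication: 17 paired 3000 s simulations for the learning-rate contrast,
three 1000 s replicate pairs for the weight-noise
experiment, 600 s sessions for the imaging-pipeline recoveries, and
10-seed batches for the regression recoveries. A single 3000 s simulation
takes on the order of ten seconds of wall time.

# Known limitations

* $\alpha$, $D$, $\beta$, the population sizes, the velocity and
  learning-rate unit conventions, and the initial-weight distribution are
  calibrated or chosen by this package, not fixed constants of the circuit;
  conclusions should rest on the operating regime, not on their exact
  magnitudes.
* The ER-to-compass pairing for the regularity metric matches azimuths
  one-to-one; the doubled-wedge anatomy of the real ellipsoid body is
  outside the model's single-ring coordinate.
* The presynaptic learning rule is a reconstruction with the documented
  gating structure, not a reprint of the referenced model's equations.
* Per-cycle MI values on slow bumps carry estimator bias (see above);
  compare windows, do not interpret absolute nats.
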