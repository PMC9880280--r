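---
title: "Multi-scale simulation of wake- and sleep-like brain states: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale simulation of wake- and sleep-like brain states: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

adexbrain simulates cortical dynamics across three scales — spiking
networks, population mean fields, and connectome-coupled whole-brain
models — and analyses the resulting activity (spectra, functional
connectivity, phase-lag index, perturbational complexity). This vignette
is the package's account of the underlying science: the models, the
calibration pipeline, the parameters that matter, and the choices made
where the design was genuinely open.

## 1. The spiking scale: conductance-based AdEx networks

The microscopic model is a network of \(N = 10^4\) adaptive exponential
integrate-and-fire (AdEx) neurons, 80% regular-spiking (RS, excitatory,
with spike-frequency adaptation) and 20% fast-spiking (FS, inhibitory,
no adaptation), randomly connected with probability \(p = 0.05\):

\[
c_m \frac{dv_k}{dt} = g_L (E_L - v_k)
 + g_L \Delta\, e^{(v_k - v_{thr})/\Delta} - w_k + I_{syn},
\qquad
u_w \frac{dw_k}{dt} = -w_k + a (v_k - E_L),
\]

with \(w_k \to w_k + b\) at each spike, detection at \(v_{peak}\), reset
to \(v_{reset}\) and a 5-ms refractory clamp. Synapses are
conductance-based: \(I_{syn} = G_e (E_e - v) + G_i (E_i - v)\), with
\(G_{e,i}\) decaying exponentially (\(u_e = u_i = 5\) ms) and jumping by
the quantal \(Q_e = 1.5\) nS / \(Q_i = 5\) nS on presynaptic spikes. All
defaults are in `adex_params()`; the single scientific knob used
throughout is the spike-triggered adaptation increment `b` (pA): at
`b = 0` the network fires asynchronously and irregularly (AI,
wake-like), at `b = 60` adaptation builds up during active periods and
silences the network until it decays, producing Up/Down slow waves
(sleep-like).

Numerics: forward Euler at `dt = 0.1` ms, with the exponential argument
clamped at +10 (consequence-free, since spikes are detected at
\(v_{peak}\) first) and exact exponential decay for the conductances.
Halving `dt` moves the 5-s mean population rate by under 2% (tested).

**External drive.** Each neuron receives an independent Poisson
excitatory stream through `Q_e` synapses, standing in for miniature
synaptic events and unresolved background input. Its rate is not a
published quantity; the package default is 0.5 Hz per drive synapse
with 400 drive synapses per neuron. The choice was calibrated once
against the regime phenomenology — at this drive the `b = 0` network
sustains AI firing (~7.5 Hz excitatory) and the `b = 60` network shows
noise-triggered Down-to-Up transitions; much weaker drive (0.3 Hz)
fails to sustain activity at all, much stronger drive (1 Hz) fills in
the Down states.

## 2. The transfer function and its calibration

The mesoscopic bridge is the population transfer function
\(F(\nu_e, \nu_i, W)\): the stationary firing rate of one neuron
receiving \(K_e = 400\) excitatory and \(K_i = 100\) inhibitory
presynaptic streams at rates \(\nu_e, \nu_i\) with adaptation current
\(W\). It is semi-analytic. The mean conductances and membrane
potential follow

\[
\mu_{Ge} = \nu_e K_e u_e Q_e, \qquad
\mu_V = \frac{\mu_{Ge} E_e + \mu_{Gi} E_i + g_L E_L - W}
             {\mu_{Ge} + \mu_{Gi} + g_L},
\]

so adaptation enters purely as a subtractive current. The fluctuation
statistics \(\sigma_V\) (potential SD) and \(\tau_V\) (autocorrelation
time) follow the standard shot-noise expressions of this model family
(per-synapse efficacy \(U_s = (Q_s/\mu_G)(E_s - \mu_V)\), effective
membrane time \(c_m/\mu_G\)). The output rate is

\[
\nu_{out} = \frac{1}{2\tau_V}\,
\mathrm{erfc}\!\left(\frac{V_{thr}^{eff} - \mu_V}{\sqrt{2}\,\sigma_V}\right),
\]

where the effective threshold \(V_{thr}^{eff}\) is a second-order
polynomial (10 coefficients) in the rescaled \((\mu_V, \sigma_V,
\tau_V g_L / c_m)\). Because the polynomial is *fitted*, small
inaccuracies in the auxiliary moment formulas are absorbed by
calibration.

`fit_tf()` measures the stationary rate of a single AdEx neuron under
Poisson bombardment on a 13 × 13 grid of input rates (0–40 Hz each,
denser at low rates) × 3 adaptation levels (0/50/100 pA for RS), 10 s
per point, averaged over 20 neurons, then fits the coefficients by
linear inversion of the erfc followed by weighted least squares. The
weights \(1/(1 + (\nu/20\,\mathrm{Hz})^2)\) matter: the inhibition-free
corner of the grid drives the neuron into a mean-driven regime above
100 Hz that the coupled model never visits, and an unweighted fit trades
accuracy in the fluctuation-driven operating region (where the balanced
network actually lives, outputs below ~30 Hz) for that corner. The
shipped default coefficients (`default_tf()`, fitted by
`scripts/fit_default_tf.R`) achieve an operating-region residual RMS of
~0.2–0.3 Hz, and reproduce held-out single-neuron simulations in the
operating band within 1 Hz RMS (tested).

What the calibration does *not* capture: in the recurrent network,
presynaptic spike trains are weakly correlated and in-degrees are
binomially distributed, whereas the calibration uses independent
Poisson trains at fixed \(K\). The residual mismatch between the
network's self-consistent operating point (~7.6 Hz) and the
transfer-function balance (~7.2–7.4 Hz) is of that origin and stays
within a few percent.

## 3. The single-region mean field

The Master Equation description evolves population rates
\(\nu_e, \nu_i\), the excitatory adaptation \(W\), and (at second
order) the 2 × 2 rate covariance \(c\):

- first order: \(T\,\dot\nu_\mu = F_\mu - \nu_\mu\),
  \(\dot W = -W/u_w + b\,\nu_e + a(\mu_V - E_L)\);
- second order adds the curvature correction
  \(\tfrac12 c_{\lambda\eta}\,\partial^2 F_\mu / \partial\nu_\lambda
  \partial\nu_\eta\) to the rate drift and evolves \(c\) with a
  finite-size source \(F_\lambda(1/T - F_\eta)/N_\lambda\)
  (\(N_e = 8000, N_i = 2000\)), a quadratic drift term, gain coupling,
  and relaxation \(-2c\). Derivatives of \(F\) are central finite
  differences with step 0.1 Hz.

The external drive is an Ornstein–Uhlenbeck process (mean 0.3 Hz, SD
0.1 Hz, correlation time 5 ms — all configurable) added to the
excitatory input argument of **both** transfer functions. The printed
single-region equations of this model family drive only the excitatory
population, but that convention contradicts the network-level coupling
(where every population receives the delayed excitatory input plus
drive) and the spiking model (where the drive reaches every neuron),
and it breaks the decoupling identity that a region with zero
inter-region coupling must behave like the single-region model. With
the consistent convention the first-order stationary rate at `b = 0`
lands within ~5% of the spiking network; with the asymmetric one it
overshoots by ~35%. The asymmetric variant remains available
(`drive_to_inhibitory = FALSE`).

Integration is stochastic Heun at `dt = 0.1` ms with the OU process
discretized exactly. Rates are clipped to \([0, 1/T_{refr}]\) — the
Master Equation's curvature correction can otherwise push them out of
the physical range — and the covariance is kept positive-semidefinite
with variances below \((100\,\mathrm{Hz})^2\) (Cauchy–Schwarz on
\(c_{ei}\)). These are the model's own physical bounds, enforced
because the calibrated transfer function is steep enough near the
balance point (rate-Jacobian spectral radius ~0.85) that the
second-order system is only marginally stable: under the default
extrinsic noise it occasionally excursions into the large-fluctuation
regime where the small-noise expansion behind the equations is invalid.
For quantitative covariance work the package therefore uses the
finite-size regime (drive SD 0; the stationary covariance then matches
an independent Lyapunov solution and is of the same order as the
spiking network's population-rate variance), and treats the noisy
second-order model as qualitative. The whole-brain analyses all use the
first-order model.

**The timescale `T`.** `T` is a phenomenological relaxation time (the
coarse-graining window of the Master Equation); nothing in the theory
pins it inside its plausible 5–40 ms range. It sets the frequency of
the coupled network's resonance, and is the package default `T = 18` ms
because that places the wake-like whole-brain spectral peak near 10 Hz
(alpha) while keeping moderate adaptation (`b = 40`) on the wake-like
side of the slow-wave transition — both regime statements of the
underlying study. At `T ≤ 16` ms the wake peak moves into beta; at
`T ≥ 20` ms with weak coupling the `b = 40` state already produces
high-amplitude delta.

`find_fixed_points()` characterizes the noise-free backbone: for each
\(\nu_e\) it solves the inhibitory balance \(\nu_i = F_i(\nu_e,\nu_i)\)
(unique root, since \(F_i\) is capped and decreasing in \(\nu_i\)),
then locates crossings of \(F_e(\nu_e, \nu_i^*(\nu_e))\) with the
identity. At the defaults and \(W = 0\) there are exactly two
crossings — a near-zero one and a stable high-rate one near 7 Hz — plus
the boundary equilibrium at exactly zero rate (reported separately as
`type = "boundary"`). Slow waves at `b = 60` are the noise-driven
alternation between the two attractors under adaptation build-up and
decay; doubling `u_w` halves the dominant frequency (tested).

## 4. The whole-brain scale

`simulate_brain()` couples one mean-field region per connectome node
through the excitatory rates only:

\[
\nu_e^{input}(k, t) = \nu_{drive}(k, t) + \nu_e(k, t)
 + S \sum_{j \neq k} C_{jk}\, \nu_e(j,\, t - d_{jk}),
\]

with self-coupling \(C_{kk} = 1\) unscaled by \(S\), delays
\(d_{jk} = \) tract length / \(v_c\) (default 3 mm/ms) rounded to the
integration step, a ring-buffer history warmed up with the initial
state, and independent per-region OU drives (one seeded RNG stream,
draws interleaved across regions). Both populations receive
\(\nu^{input}_e + \nu_{aff}\); a square-wave stimulus adds its
amplitude to the excitatory-population input of its target region only.
The inter-region coupling `S` is phenomenological; the default
`S = 0.15` was calibrated jointly with `T` against the spectral
signatures (sleep-like delta peak mid-band, wake-like alpha peak) and
then frozen.

## 5. The synthetic connectome

Tests and the acceptance pipeline must run without downloads, so
`generate_synthetic_connectome()` builds a stand-in for an empirical
68-region DTI connectome: centres sampled in two mirrored ellipsoids
(hemispheres), tract lengths = Euclidean distance × 1.3 (tortuosity),
weights log-normal (heavy-tailed, skewness > 1), decaying with distance
(length constant 60 mm), halved between hemispheres, symmetrized,
rescaled to max 1. Volumes are log-normal around 5000 mm³.

What it deliberately does **not** emulate: the specific graph structure
of a measured connectome — notably the disproportionately strong
homotopic (mirror-pair) callosal connections and hub organization of
real cortex. Consequences observed in this package: the sleep-like
phase-lag index rises with distance and its *distance structure* is
significant and abolished by row-shuffling (as with the empirical
connectome), but the empirical mid-range (~65 mm) PLI *peak* — middle
bin above both shorter and longer distances — does not emerge; on the
synthetic graph the middle bin exceeds shorter but not longer
distances. Passing tests on the synthetic connectome therefore
demonstrate the machinery and the adaptation-driven regime physics, not
connectome-specific spatial statistics. A TVB-format connectivity
directory (weights.txt / tract_lengths.txt / centres.txt) of a real
subject can be dropped in via `load_connectome()`.

## 6. Stimulus-response analysis and PCI

`run_trials()` delivers the same square pulse (default 0.1 Hz, 50 ms)
at a randomized onset in independent-noise trials and aligns ±300-ms
windows. `binarize_response()` z-scores each trial by its pre-stimulus
mean and SD averaged over regions, then thresholds post-stimulus
activity against a shuffled null: per series of 20 trials, each of 500
repetitions reassembles a surrogate epoch from the pooled,
time-randomized pre-stimulus samples, and the significance threshold is
the one-tail 99th percentile of the surrogate-epoch maxima. This
max-statistic construction keeps the null false-positive rate far below
1% (tested); note that a literal per-trial shuffle would leave the
per-trial maximum invariant and make the repetitions vacuous, which is
why the null pools the series. The percentile is configurable.

The perturbational complexity index of a trial's concatenated
significance vector \(S\) is \(\mathrm{PCI} = LZ(S)/H(S)\): an
LZ78-style sequential dictionary parse (trailing incomplete word
counted; verified exhaustively against a brute-force parser up to 12
bits) over the plug-in binary source entropy, with \(H = 0 \Rightarrow
\mathrm{PCI} = 0\) by convention (a response with no information
carries no complexity). Because \(H\) appears in the denominator,
near-empty significance vectors produce very large PCI values; PCI is
therefore compared across conditions by medians and by *relative*
spread (coefficient of variation), not raw variance. In the default
experiment (40 trials, amplitude 0.1 Hz) the median PCI decreases with
adaptation and collapses at `b = 60`, with a larger relative spread in
the sleep-like condition — less reliable stimulus encoding.

`onset_map()` reports, per region, the first post-stimulus bin
significant for ≥ 2 consecutive bins (single-bin noise suppressed),
per trial and aggregated (median over trials, requiring ≥ 25% of trials
to respond).

## 7. Statistics

Kruskal–Wallis omnibus and Mann–Whitney U tests come from base R. The
Conover–Iman all-pairs post-hoc test is implemented in the package
(rank-based t statistics with the pooled rank variance deflated by the
Kruskal–Wallis statistic, df = N − k, Holm-adjusted by default), since
no installed package provides it. The excitatory-vs-inhibitory
functional-connectivity comparison is an independent two-sample t-test
over off-diagonal entries with the excitatory-minus-inhibitory sign
convention.

Spectra are Welch periodograms (4-s Hann windows, 50% overlap,
one-sided density; integrated density matches the series variance,
tested) on the region-averaged excitatory rate sampled at 1 kHz. The
phase-lag index uses FFT-based Hilbert phases,
\(\mathrm{PLI}_{ij} = |\langle \mathrm{sign}\,
\sin(\psi_i - \psi_j)\rangle|\) over 1-s epochs, averaged across
epochs; the sine handles phase wrapping and makes the index invariant
under a common phase shift.

## 8. Problem sizes and reproducibility

Every stochastic function takes an explicit seed and is bit-reproducible
for fixed inputs. The shipped analyses use: 5-s spiking runs at
\(N = 10^4\); 10–12-s single-region and 68-region simulations (2-s
transient discard); 40-trial PCI ensembles per condition; the scan
driver defaults to 7-s runs per configuration and supports arbitrary
sub-grids of the (S, E_L_e, E_L_i, T, b_e) space — the full
16-values-per-axis factorial is intended to be sharded across many such
sub-grid invocations. These sizes keep a complete reproduction
(`scripts/acceptance.R`) within tens of minutes on one CPU while leaving
every regime comparison at the scale the underlying study states.

## 9. Known limitations

- The mean field inherits the validity limits of its derivation: it is
  inaccurate for adaptation beyond ~100 pA and for fast synchronous
  oscillations (gamma, spindles); the second-order covariance is
  quantitative only in the finite-size (weak extrinsic noise) regime.
- The transfer-function calibration covers inputs up to 40 Hz per
  population; outside the fitted domain the polynomial extrapolates and
  the fixed-point scan deliberately treats high-rate crossings with
  suspicion.
- Synthetic-connectome results are not subject-specific; spatial
  statistics tied to real tract geometry (homotopic PLI peaks,
  hemisphere-block correlation structure) require an empirical
  connectivity matrix.
- Regions share one parameter set (no regional heterogeneity), and
  inhibition stays local to each region by construction.
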