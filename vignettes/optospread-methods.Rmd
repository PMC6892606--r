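---
title: "Models and estimators in optospread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in optospread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optospread)
```

`optospread` quantifies how far and how fast optogenetic silencing spreads in
cortex. This vignette is the package's account of the science inside it: the
models, the estimators and their numerical choices, what the synthetic
generators do and do not emulate, and the known limitations.

## 1. Light in tissue from photobleaching

### Model

Prolonged illumination photobleaches fluorescent proteins. At constant
illumination the surviving fluorophore fraction decays exponentially in the
light dose (intensity × time), so the fractional fluorescence change of a
nucleus at position $r$ is

$$ f(r) = \frac{\Delta F}{F_0} = -1 + e^{-k\,I(r)\,T}, $$

with $I(r)$ the relative light intensity, $T$ the dose and $k$ a
fluorophore-specific bleaching constant. Inverting,

$$ I(r) \propto -\ln\!\big(f(r) + 1\big), $$

where the proportionality constant ($kT$) is absorbed by normalizing the
recovered field to 1 at its maximum. `fit_bleach_constant()` estimates $k$
by nonlinear least squares of $f = -1 + e^{-k\,\text{dose}}$ on
center-ROI measurements across doses; separate fits per fluorophore and
wavelength are expected (GFP at 473 nm, mCherry at 594 nm).

The baseline $F_0$ is the mean fluorescence of ROIs more than 700 µm from
the laser center (`compute_dff()`, configurable). Distance is 3-D Euclidean
by default; a `"lateral"` mode uses lateral distance only, the convention
for strongly bleaching (orange-light) volumes whose deep on-axis ROIs are
not trustworthy baselines. $f$ is kept signed (bleaching negative).

### Numerical choices

* **Gridding.** ROI intensities $-\ln(f+1)$ are averaged into cubic voxels
  (25 µm default; voxel $k$ spans $[(k-1)\Delta, k\Delta)$). Empty voxels
  are filled by iterative averaging of their six face-adjacent nonempty
  neighbors — inverse-distance interpolation at equal distances — which
  scales to the $100^3$ grids of large volumes.
* **Clipping.** ROIs with $f \le -0.99$ (near-complete bleach; the log
  diverges) are excluded and counted; noise-driven $f > 0$ values would
  invert to negative intensity and are clamped to zero.
* **Profile summaries.** `profile_summary()` reports the half-max depth
  (on-axis intensity falling to half its surface value) and the lateral 50%
  distance at a reference depth (200 µm default). Reading single voxel
  planes from a sparse noisy grid is badly biased: the half-covered surface
  plane underestimates the surface reference and inflates every normalized
  depth. Instead (i) the surface value is a log-linear extrapolation of the
  near-surface axial profile to $z = 0$; (ii) the on-axis reference at the
  comparison depth is a log-linear-in-$r^2$ extrapolation of the inner
  radial profile to $r = 0$ (exact for exponential / Gaussian forms);
  (iii) the on-axis profile is averaged over a disc whose radius adapts to
  half the field's surface lateral half-width — for a laterally separable
  field, disc averaging rescales all depths equally and cancels in the
  ratios, so a wider disc is pure variance reduction for broad beams; and
  (iv) the axial crossing is refined by a local log-linear regression over
  the planes bracketing it, since attenuation with depth is locally
  exponential. A 3-plane running mean stabilizes crossing detection; the
  lateral profile averages a 5-plane slab.
* **Degenerate inputs.** Uniform fields, fields that never fall below half,
  and flat $\Delta F/F_0$ maps raise errors that report the bound actually
  established.

### Limitations

Photobleaching has limited dynamic range: a long low-intensity tail that
still gates opsins is below the noise floor of this method, so recovered
profiles understate the far reach of the light. The separable
axial-exponential × lateral-Gaussian synthetic field is an explicit
simplification — no photon transport, wavelength-dependent scattering
anisotropy, or hemoglobin absorption spectra are modeled.

## 2. Spike-width classification

Width is the trough-to-peak interval of the mean waveform
(`trough_to_peak()`, optional 10× cubic-spline refinement; waveforms are
expected at the 19531.25 Hz sampling of multiplexed silicon-probe
recordings). Units with width < 0.35 ms are putative fast-spiking (FS)
interneurons, > 0.45 ms putative pyramidal; both inequalities are strict and
the closed band [0.35, 0.45] ms is excluded (`UNCLASSIFIED`). Waveforms
whose global maximum precedes the trough, or that never recover after it,
are rejected as non-spike-like. Somatostatin-positive interneurons cannot be
separated by width alone; no third class is attempted.

## 3. Inactivation metrics

* **Relative spike rate.** Per unit: stimulus-window rate divided by the
  baseline rate (500 ms before onset). Population: rates averaged across
  units first, then the ratio taken — the total fraction of spiking output,
  equal to the baseline-rate-weighted mean of unit ratios. Units with zero
  baseline are excluded from unit-level ratios (flagged) but participate in
  population sums, which need no per-unit division. The stimulus window
  excludes the terminal intensity ramp by default.
* **Spatial profile and half-max radius.** Units are binned by lateral
  distance (0.25 mm bins from 0 by default); each bin gets the population
  relative rate with a bootstrap s.e.m. from resampling units within the
  bin. The half-max radius is the smallest distance at which the reduction
  $d(r) = 1 - R(r)$ falls to half its center value (innermost bin by
  default, configurable), located by linear interpolation between bin
  centers; its uncertainty comes from resampling units with replacement
  (2000 resamples, central 90% interval), recomputing profile and radius
  each time.
* **Onset latency.** The reference level is
  $b - 0.9\,(b - \bar{m})$, with $b$ the baseline PSTH rate and $\bar{m}$
  the mean rate over the whole photostimulation period; onset is the first
  post-onset time the PSTH falls to that level. On a raw 1 ms PSTH the
  first-passage reading is biased early by several ms — single-bin Poisson
  dips cross the threshold before the underlying rate does — so the
  crossing is located on a cubic smoothing-spline estimate of the rate
  (8 effective degrees of freedom over the first 100 ms), which leaves the
  noiseless closed-form crossing within 0.25 ms while removing the
  first-passage bias. Coarse PSTHs fall back to a raw crossing that must be
  sustained for 4 ms.
* **Earliest change.** First 10 ms bin whose across-unit rates differ from
  per-unit baselines by a paired two-tailed t-test at $\alpha = 0.05$; no
  multiple-testing correction is applied, deliberately mirroring the
  convention for this statistic, so its per-bin false-positive rate is
  $\approx \alpha$ (tested). FS excitation onsets conventionally use 1 ms
  bins.
* **Rebound.** $(\text{post} - \text{base})/\text{base}$ over a 500 ms
  window after offset, averaged across units.
* **Intensity conversion.** Reported intensities divide power by
  $2\pi r^2$ with $r = 1$ mm. A disc of radius $r$ has area $\pi r^2$; the
  published convention is nonetheless $2\pi r^2$ and is implemented as
  printed, with a `"disc"` flag (exactly 2× the default) for sensitivity
  checks. The intent behind the printed formula is not guessed.
* **Paradoxical scan.** Population relative rates per class per light
  intensity; the paradoxical regime is the maximal initial intensity range
  over which the FS rate is non-increasing while the pyramidal rate
  decreases, and the FS-minimum intensity is reported. Levels missing a
  class are dropped and logged.

## 4. The E–I rate network

The paper-level claim being emulated — FS rates falling together with
pyramidal rates until pyramidal activity is nearly silenced, then rising —
is the signature of an inhibition-stabilized network (ISN). The package's
model (its own construction; the underlying circuit equations are not
constrained by data here) is the simplest one exhibiting it: rectified-linear
rate dynamics with unit gain,

$$ \tau \dot r = -r + \big[W r + h + g_\text{opsin} L\big]_+ ,\qquad
   W = \begin{pmatrix} w_{EE} & -w_{EI} \\ w_{IE} & -w_{II} \end{pmatrix}. $$

In the fully active branch the fixed point solves $(I - W) r = h$, and the
response of $r_I$ to drive on I is $(1 - w_{EE})/\det(I - W)$: negative —
paradoxical — exactly when the excitatory subnetwork is unstable alone
($w_{EE} > 1$) and stabilized by feedback inhibition. Steady states are
found by damped iteration (Euler steps of $\tau_{\min}/20$, convergence at
$\max|\Delta r| < 10^{-10}$, divergence and non-convergence reported with
the parameter set); a stability flag checks the Jacobian eigenvalues of the
active linear branch. `isn_simulate()` integrates the same dynamics with
explicit Euler ($dt \le \tau_{\min}/10$ enforced; the integrator is
deliberately simple and swappable), applies the 40 Hz raised-cosine opsin
drive at unit mean (reported powers are time averages) and the terminal
linear ramp.

The spatial extension places both populations on a 1-D lateral grid
(distance is the measured axis) with Gaussian coupling kernels,
row-normalized so each kernel's row sums equal the scalar weight; kernel
widths → 0 recovers independent two-population nodes (tested to $10^{-8}$).
Which interneuron subtypes the I population stands for is left open — PV and
Sst differences are outside the model's scope.

## 5. Synthetic data: what it emulates, what it does not

`simulate_suppression_dataset()` draws inhomogeneous-Poisson spikes (via
thinning, with a 1 ms absolute refractory period imposed by deletion to
avoid pathological ISIs) from parametric rate trajectories: exponential
approach (time constant `onset_tau_ms`) to
$b\,[1 - c\,e^{-r^2/2\sigma^2}]$ during the stimulus, exponential rebound
$b\,[1 + a\,e^{-t/\tau_\text{reb}}]$ after offset, FS units mirrored upward
with gain `fs_activation_gain` (and, unlike the parametric pyramidal
trajectories, no post-offset rebound — they relax to baseline). The
parametric backend treats power as time-averaged; the 40 Hz modulation only
matters to the ISN backend (`simulate_isn_datasets()`), which sets per-class
rates from network steady states instead.

Defaults are the study conditions the package targets: 90% center
reduction, lateral $\sigma = 0.68$ mm, 8 ms onset, 1.3 s stimulus, 50
trials, distances 0–2.5 mm in 0.1 mm steps, 20 pyramidal units per
distance. Where no value is dictated by those conditions, conventional
choices are made once and flagged: pyramidal baseline 8 Hz and FS 15 Hz
with gamma-distributed across-unit variability (shape 4), lognormal
nucleus baseline fluorescence with CV 0.2, 10% multiplicative ROI noise,
waveform widths drawn outside the exclusion band (FS 0.20–0.32 ms,
pyramidal 0.50–0.70 ms).

What passing tests on these data do **not** show: real recordings have
non-Poisson count dispersion, correlated noise across units and bins,
drifting baselines, spike-sorting contamination, and suppression profiles
that need not be Gaussian; the generators make none of these, so the tests
certify the estimators' correctness and calibration under the stated model,
not robustness to every property of in vivo data.

## 6. Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use the generators at the sizes
the synthetic experiments specify — 20,000 nuclei per bleaching volume;
100 units × 100 trials for the onset estimate; 26 distances × 20 units ×
50 trials with 2000 bootstrap resamples for the half-max radius; 500
repetitions for bootstrap-coverage checks — which keep every run
single-CPU and fast while leaving sampling error well inside the tested
tolerances. Every stochastic step takes an explicit seed; dataset metadata
echoes the generator seed and config, pipeline outputs embed a config hash,
and a single `--seed` drives all randomness in the acceptance script.
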