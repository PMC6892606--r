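# optospread

Quantifying the spatial and temporal spread of optogenetic cortical
inactivation.

Optogenetic silencing — exciting GABAergic interneurons with ChR2/ReaChR, or
directly hyperpolarizing pyramidal neurons with GtACR1, Arch or Jaws — is
routinely treated as a local manipulation. In practice the silenced volume is
set jointly by how far the photostimulus light spreads in tissue and by how
strongly cortical neurons are coupled: suppression reaches millimeters beyond
the beam. `optospread` implements the quantitative pipeline needed to
characterize both contributions:

1. **Light in tissue from photobleaching.** Prolonged illumination bleaches
   nuclear-targeted fluorophores. Bleaching is exponential in light dose,

   `f(r) = ΔF/F₀ = −1 + exp(−k·I(r)·T)`,

   so the relative intensity profile is recovered as
   `I(r) ∝ −ln(f(r) + 1)`, with `F₀` taken from ROIs > 700 µm from the laser
   center and `k` fitted per fluorophore from center ΔF/F₀ versus dose
   (`compute_dff()`, `fit_bleach_constant()`, `invert_intensity()`,
   `profile_summary()`).
2. **Cell-type classification.** Trough-to-peak spike width on the mean
   waveform; width < 0.35 ms → fast-spiking (FS), > 0.45 ms → putative
   pyramidal, the closed band in between excluded (`trough_to_peak()`,
   `classify_unit()`).
3. **Inactivation metrics.** Relative spike rate (per-unit, and the
   population convention `mean(stim rates)/mean(baseline rates)`), spatial
   profiles versus lateral distance with unit-resampling bootstrap, the
   half-max radius of suppression, PSTH onset latency by the
   90%-of-average-reduction rule, earliest significant change (10 ms bins,
   across-unit t-test), rebound index after stimulus offset, and a
   paradoxical-effect scan across light intensities
   (`spatial_profile()`, `half_max_radius()`, `onset_latency()`,
   `rebound_index()`, `paradoxical_scan()`).
4. **Generators and network model.** Synthetic bleached-nuclei volumes and
   inhomogeneous-Poisson spike datasets with configurable suppression
   structure (`make_nuclei_volume()`, `bleach_forward()`,
   `simulate_suppression_dataset()`), plus a rectified-linear
   excitatory–inhibitory rate network whose inhibition-stabilized regime
   (`w_EE > 1`) reproduces the paradoxical effect — driving inhibitory cells
   *lowers* their steady-state rate, `∂r_I/∂h_I = (1 − w_EE)/det(I − W) < 0`
   (`isn_params()`, `isn_steady_state()`, `isn_simulate()`).

## Worked example

```r
library(optospread)

# blue-light photobleaching volume -> recovered intensity profile
blue <- function(x, y, z) exp(-z / 433) * exp(-(x^2 + y^2) / (2 * 114.7^2))
vol  <- make_nuclei_volume(20000, c(1200, 1200, 1000), seed = 1)
rois <- bleach_forward(vol, blue, k_dose = 3 / 200, dose = 200,
                       noise_cv = 0.10, seed = 16)
dff  <- compute_dff(rois, far_threshold_um = 700)
prof <- profile_summary(invert_intensity(dff))
round(c(depth = prof$half_max_depth_um, lateral = prof$lateral_half_width_um), 1)
#>   depth lateral
#>   304.4   137.2

# spatial spread of suppression -> half-max radius with bootstrap CI
cfg <- suppression_config(center_reduction = 0.9, lateral_sigma_mm = 0.68,
                          onset_tau_ms = 1e-3, rebound_amplitude = 0,
                          n_fs_per_distance = 0, seed = 4)
ds  <- simulate_suppression_dataset(cfg, photostim_protocol(duration_s = 1.3,
                                                            ramp_ms = 0))
sp  <- spatial_profile(ds, units = "PYR", n_boot = 1000, seed = 4)
half_max_radius(sp, n_resamples = 2000, seed = 4)$radius_mm
#> [1] 0.8273184

# the paradoxical effect in an inhibition-stabilized network
p <- isn_params(w_ee = 2, w_ei = 2.5, w_ie = 3, w_ii = 2, h_e = 1, h_i = 0)
isn_steady_state(p, light = 0)$rates      # E 0.667, I 0.667
isn_steady_state(p, light = 0.45)$rates   # E 0.417, I 0.567 -- I *falls*
```

The first block says: with ~95% bleaching at the center and 10% measurement
noise, the recovered blue-light field falls to half its surface intensity at
~300 µm depth and to half its on-axis value at ~135 µm laterally (0.2 mm
depth). The second: a 90% center suppression with Gaussian lateral scale
0.68 mm has a half-max radius of ~0.8 mm. The third is the ISN signature:
adding drive to the inhibitory population lowers its own rate.

A YAML-configured end-to-end run (simulate → classify → metrics → JSON
report) is available through `run_pipeline()`.

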