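# Synthetic-data generators: nuclei volumes, bleaching forward model,
# inhomogeneous Poisson sampling, suppression datasets.

test_that("make_nuclei_volume places the requested nuclei inside the volume", {
  empty <- make_nuclei_volume(0, c(100, 100, 100), seed = 1)
  expect_equal(nrow(empty$positions), 0L)

  vol <- make_nuclei_volume(100, c(1000, 1000, 1000), seed = 1)
  expect_equal(nrow(vol$positions), 100L)
  expect_true(all(abs(vol$positions[, "x_um"]) <= 500))
  expect_true(all(abs(vol$positions[, "y_um"]) <= 500))
  expect_true(all(vol$positions[, "z_um"] >= 0 &
                    vol$positions[, "z_um"] <= 1000))
  expect_true(all(vol$baseline_fluorescence > 0))

  expect_error(make_nuclei_volume(-1, c(1, 1, 1)), "integer|>=")
  expect_error(make_nuclei_volume(10, c(0, 1, 1)), "positive")
})

test_that("nuclei density is uniform across octants (3 binomial s.d.)", {
  n <- 20000
  dims <- c(1200, 1200, 1000)
  vol <- make_nuclei_volume(n, dims, seed = 7)
  p <- vol$positions
  oct <- paste(p[, 1] > 0, p[, 2] > 0, p[, 3] > dims[3] / 2)
  counts <- table(oct)
  expect_equal(length(counts), 8L)
  expected <- n / 8
  tol <- 3 * sqrt(n * (1 / 8) * (7 / 8))
  expect_true(all(abs(counts - expected) < tol))
})

test_that("bleach_forward follows the exponential dose model", {
  vol <- make_nuclei_volume(200, c(400, 400, 400), seed = 2, baseline_cv = 0)
  # no light: fluorescence unchanged
  dark <- bleach_forward(vol, function(x, y, z) 0 * x, k_dose = 1, dose = 10)
  expect_equal(dark$F, vol$baseline_fluorescence, tolerance = 1e-12)
  # k I T = 1 at every nucleus: dF/F0 = exp(-1) - 1
  one <- bleach_forward(vol, function(x, y, z) 0 * x + 1, k_dose = 0.1,
                        dose = 10)
  f <- one$F / vol$baseline_fluorescence - 1
  expect_equal(f, rep(exp(-1) - 1, 200), tolerance = 1e-12)
  # saturating dose: fluorescence -> 0
  sat <- bleach_forward(vol, function(x, y, z) 0 * x + 1, k_dose = 1,
                        dose = 1e4)
  expect_true(all(sat$F < 1e-6))
  expect_error(bleach_forward(vol, function(x, y, z) 0 * x, k_dose = 1,
                              dose = -1), ">=")
  expect_error(bleach_forward(vol, function(x, y, z) 0 * x + 2, k_dose = 1,
                              dose = 1), "\\[0, 1\\]")
})

test_that("inhomogeneous Poisson sampler matches count statistics", {
  none <- sample_inhomogeneous_poisson(function(t) 0 * t, 10, 5, seed = 1)
  expect_true(all(lengths(none) == 0))

  tr <- sample_inhomogeneous_poisson(function(t) 10 + 0 * t, 100, 1,
                                     seed = 2, refractory_ms = 0)
  expect_true(abs(length(tr[[1]]) - 1000) < 4 * sqrt(1000))
  expect_false(is.unsorted(tr[[1]]))

  expect_error(sample_inhomogeneous_poisson(function(t) -1 + 0 * t, 1, 1,
                                            seed = 1), "nonnegative")
})

test_that("sinusoidal-rate spikes pass the time-rescaling KS oracle", {
  rate <- function(t) 20 + 10 * sin(2 * pi * 2 * t)
  trains <- sample_inhomogeneous_poisson(rate, 50, 20, seed = 3,
                                         refractory_ms = 0)
  # time-rescaling: Lambda(t) intervals of a Poisson process are Exp(1)
  Lambda <- function(t) 20 * t + 10 / (2 * pi * 2) * (1 - cos(2 * pi * 2 * t))
  u <- unlist(lapply(trains, function(st) diff(Lambda(st))))
  expect_gt(length(u), 5000)
  ks <- suppressWarnings(stats::ks.test(u, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("refractory deletion enforces the minimum inter-spike interval", {
  tr <- sample_inhomogeneous_poisson(function(t) 200 + 0 * t, 10, 3, seed = 4,
                                     refractory_ms = 1)
  isis <- unlist(lapply(tr, diff))
  expect_true(all(isis >= 1e-3 - 1e-12))
})

test_that("suppression generator honors its rate contract", {
  # null suppression: stimulus-window rates match baseline within 3 sigma
  cfg0 <- suppression_config(center_reduction = 0, rebound_amplitude = 0,
                             n_units_per_distance = 10, n_fs_per_distance = 0,
                             distances_mm = c(0, 1), n_trials = 40, seed = 5)
  ds0 <- simulate_suppression_dataset(cfg0,
                                      photostim_protocol(duration_s = 1.3,
                                                         ramp_ms = 0))
  rel0 <- relative_rate_population(ds0)
  expect_true(abs(rel0 - 1) < 0.07)  # ~3 sigma at these spike counts

  # 90% center reduction at r = 0: empirical relative rate ~ 0.10
  cfg9 <- suppression_config(center_reduction = 0.9, onset_tau_ms = 1e-3,
                             rebound_amplitude = 0,
                             n_units_per_distance = 30, n_fs_per_distance = 0,
                             distances_mm = 0, n_trials = 60, seed = 6)
  ds9 <- simulate_suppression_dataset(cfg9,
                                      photostim_protocol(duration_s = 1.3,
                                                         ramp_ms = 0))
  expect_equal(relative_rate_population(ds9), 0.10, tolerance = 0.15)

  # rebound contract: amplitude 0.3 with long tau -> index ~ 0.3
  cfgr <- suppression_config(center_reduction = 0.5,
                             rebound_amplitude = 0.3, rebound_tau_ms = 1e4,
                             n_units_per_distance = 60, n_fs_per_distance = 0,
                             distances_mm = 0, n_trials = 60, seed = 7)
  dsr <- simulate_suppression_dataset(cfgr,
                                      photostim_protocol(duration_s = 1.3,
                                                         ramp_ms = 0))
  expect_equal(rebound_index(dsr), 0.3, tolerance = 0.12)
})

test_that("same seed reproduces the dataset exactly", {
  cfg <- suppression_config(n_units_per_distance = 4, n_fs_per_distance = 2,
                            distances_mm = c(0, 0.5), n_trials = 5, seed = 42)
  d1 <- simulate_suppression_dataset(cfg)
  d2 <- simulate_suppression_dataset(cfg)
  expect_identical(d1$spikes, d2$spikes)
  expect_identical(d1$units, d2$units)
  expect_identical(d1$waveforms, d2$waveforms)
})

test_that("generated empirical rates converge to configured trajectories", {
  cfg <- suppression_config(center_reduction = 0.8, onset_tau_ms = 1e-3,
                            rebound_amplitude = 0, lateral_sigma_mm = 0.68,
                            n_units_per_distance = 1, n_fs_per_distance = 0,
                            distances_mm = c(0, 0.68, 1.5), n_trials = 500,
                            seed = 8)
  ds <- simulate_suppression_dataset(cfg,
                                     photostim_protocol(duration_s = 1.3,
                                                        ramp_ms = 0))
  base <- optospread:::unit_window_rates(ds, c(-0.5, 0))
  stim <- optospread:::unit_window_rates(ds, c(0, 1.3))
  r_mm <- ds$units$lateral_distance_um / 1000
  target <- 1 - 0.8 * exp(-r_mm^2 / (2 * 0.68^2))
  for (u in seq_along(base)) {
    expected <- ds$units$baseline_rate_true_hz[u] * target[u]
    sigma <- sqrt(expected / (500 * 1.3))   # Poisson s.e. of the rate
    expect_true(abs(stim[u] - expected) < 3 * sigma + 0.05,
                label = sprintf("unit %d rate within 3 sigma", u))
  }
})
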