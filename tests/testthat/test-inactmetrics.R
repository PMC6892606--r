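# PSTHs, relative spike rates, rebound, latencies, half-max radius,
# bootstrap machinery.

test_that("compute_psth counts spikes into the right bins", {
  # one spike per trial at t = +5 ms: single nonzero 1 ms bin at [5, 6)
  ds <- spike_dataset(
    units = data.frame(unit_id = 1, lateral_distance_um = 0, depth_um = 0),
    spikes = data.frame(unit_id = 1, trial_id = 1:4, spike_time_s = 0.0055),
    trials = data.frame(trial_id = 1:4, condition_id = "c1"),
    conditions = list(c1 = photostim_protocol(duration_s = 0.1, ramp_ms = 0)),
    metadata = list(trial_window_s = c(-0.05, 0.1)))
  ps <- compute_psth(ds, bin_ms = 1, window = c(0, 20))
  ctr <- ps$bin_edges_ms[-length(ps$bin_edges_ms)]
  expect_equal(ps$rate_hz[ctr == 5], 1000)  # 1 spike / (4 trials * 1 ms) * 4
  expect_equal(sum(ps$rate_hz > 0), 1L)

  # no spikes -> all-zero PSTH
  empty <- ds
  empty$spikes <- empty$spikes[0, ]
  expect_true(all(compute_psth(empty, bin_ms = 1,
                               window = c(0, 20))$rate_hz == 0))
  expect_error(compute_psth(ds, units = integer(0)), "empty")
})

test_that("homogeneous Poisson PSTH sits at its rate", {
  trains <- sample_inhomogeneous_poisson(function(t) 10 + 0 * t, 2, 200,
                                         seed = 5, refractory_ms = 0)
  spikes <- data.frame(
    unit_id = 1,
    trial_id = rep(seq_along(trains), lengths(trains)),
    spike_time_s = unlist(trains))
  ds <- spike_dataset(
    units = data.frame(unit_id = 1, lateral_distance_um = 0, depth_um = 0),
    spikes = spikes,
    trials = data.frame(trial_id = 1:200, condition_id = "c1"),
    conditions = list(c1 = photostim_protocol(duration_s = 2, ramp_ms = 0)),
    metadata = list(trial_window_s = c(0, 2)))
  ps <- compute_psth(ds, bin_ms = 50, window = c(0, 2000))
  # mean bin rate within 3 sigma of 10 Hz
  n_bins <- length(ps$rate_hz)
  sem <- sqrt(10 / (200 * 2))
  expect_lt(abs(mean(ps$rate_hz) - 10), 3 * sem)
})

test_that("relative spike rate conventions differ as designed", {
  # units: (base 10, stim 0) and (base 2, stim 2)
  ds <- tiny_dataset(stim_rates = c(0, 2), base_rates = c(10, 2))
  unit_ratios <- relative_rate_unit(ds)
  expect_equal(unname(unit_ratios), c(0, 1), ignore_attr = TRUE)
  # population convention: (0 + 2) / (10 + 2), not mean of unit ratios (0.5)
  expect_equal(relative_rate_population(ds), 2 / 12, tolerance = 1e-10)

  same <- tiny_dataset(stim_rates = c(4, 6), base_rates = c(4, 6))
  expect_equal(relative_rate_population(same), 1)
  expect_equal(unname(relative_rate_unit(same)), c(1, 1),
               ignore_attr = TRUE)

  silenced <- tiny_dataset(stim_rates = c(0, 0), base_rates = c(10, 2))
  expect_equal(relative_rate_population(silenced), 0)

  # activated FS unit: ratio above 1
  fs <- tiny_dataset(stim_rates = 30, base_rates = 10)
  expect_equal(unname(relative_rate_unit(fs)), 3, ignore_attr = TRUE)

  # zero-baseline unit: NA in unit ratios, still counted in population sums
  zb <- tiny_dataset(stim_rates = c(2, 4), base_rates = c(0, 8))
  ru <- relative_rate_unit(zb)
  expect_true(is.na(ru[1]))
  expect_equal(attr(ru, "n_zero_baseline"), 1L)
  expect_equal(relative_rate_population(zb), 6 / 8)
})

test_that("population relative rate equals baseline-weighted mean of ratios", {
  cfg <- suppression_config(n_units_per_distance = 15, n_fs_per_distance = 0,
                            distances_mm = c(0, 0.4, 1), n_trials = 10,
                            seed = 12)
  ds <- simulate_suppression_dataset(cfg)
  base <- optospread:::unit_window_rates(ds, c(-0.5, 0))
  ratios <- relative_rate_unit(ds)
  ok <- base > 0
  weighted <- sum(base[ok] * ratios[ok]) / sum(base)
  expect_equal(relative_rate_population(ds), weighted, tolerance = 1e-10)
})

test_that("rebound index is the normalized post-offset rate change", {
  # post = base -> 0; base 10 post 13 -> 0.3; base 10 post 8 -> -0.2
  mk <- function(post_rate) {
    # 2 trials, 0.5 s post window: pooled rate = count / (2 * 0.5) = count
    ds <- tiny_dataset(stim_rates = 5, base_rates = 10, duration_s = 1,
                       n_trials = 2)
    post <- data.frame(unit_id = 1, trial_id = 1,
                       spike_time_s = seq(1.001, 1.499,
                                          length.out = post_rate))
    ds$spikes <- rbind(ds$spikes, post)
    ds
  }
  expect_equal(rebound_index(mk(10)), 0)
  expect_equal(rebound_index(mk(13)), 0.3, tolerance = 1e-10)
  expect_equal(rebound_index(mk(8)), -0.2, tolerance = 1e-10)
})

test_that("intensity_from_power follows the published convention", {
  expect_equal(intensity_from_power(2 * pi, 1), 1)
  expect_equal(intensity_from_power(6.2832, 1), 1, tolerance = 1e-4)
  expect_equal(intensity_from_power(0, 1), 0)
  # disc-area alternative is exactly twice the published convention
  expect_equal(intensity_from_power(3, 1, convention = "disc"),
               2 * intensity_from_power(3, 1))
  expect_error(intensity_from_power(1, 0), "> 0")
})

test_that("onset latency matches the closed-form crossing on noiseless data", {
  # exponential suppression tau = 8 ms, baseline 8 Hz, asymptote 0.8 Hz
  ctr_rate <- function(t) 0.8 + 7.2 * exp(-pmax(t, 0) / 8)
  edges <- seq(-500, 1300, by = 1)
  ctr <- edges[-length(edges)] + 0.5
  rate <- ifelse(ctr < 0, 8, ctr_rate(ctr))
  ps <- structure(list(bin_edges_ms = edges, rate_hz = rate,
                       unit_rate_hz = matrix(rate, 1), n_units = 1,
                       n_trials = 1, bin_ms = 1), class = "psth")
  m <- mean(rate[ctr >= 0])
  ref <- 8 - 0.9 * (8 - m)
  t_true <- 8 * log(7.2 / (ref - 0.8))
  expect_equal(t_true, 18, tolerance = 0.03)
  expect_lt(abs(onset_latency(ps, stim_ms = c(0, 1300)) - t_true), 0.5)
  expect_lt(abs(onset_latency(ps, stim_ms = c(0, 1300), method = "raw") -
                  t_true), 0.5)

  # step suppression: onset within one bin width
  step <- ifelse(ctr < 0, 8, 0.4)
  ps_step <- structure(list(bin_edges_ms = edges, rate_hz = step,
                            unit_rate_hz = matrix(step, 1), n_units = 1,
                            n_trials = 1, bin_ms = 1), class = "psth")
  expect_lte(onset_latency(ps_step, stim_ms = c(0, 1300)), 1)

  # activity increase: latency undefined
  up <- ifelse(ctr < 0, 8, 12)
  ps_up <- structure(list(bin_edges_ms = edges, rate_hz = up,
                          unit_rate_hz = matrix(up, 1), n_units = 1,
                          n_trials = 1, bin_ms = 1), class = "psth")
  expect_error(onset_latency(ps_up, stim_ms = c(0, 1300)), "increase")
})

test_that("earliest significant change finds strong immediate suppression", {
  cfg <- suppression_config(center_reduction = 0.95, onset_tau_ms = 1e-3,
                            rebound_amplitude = 0, n_units_per_distance = 100,
                            n_fs_per_distance = 0, distances_mm = 0,
                            n_trials = 30, seed = 13)
  ds <- simulate_suppression_dataset(cfg)
  expect_equal(earliest_significant_change(ds, bin_ms = 10), 0)

  one_unit <- optospread:::filter_units(ds, 1L)
  expect_error(earliest_significant_change(one_unit), ">= 2 units")
})

test_that("earliest-change per-bin false-positive rate is near alpha", {
  # null data: no suppression at all
  n_sig <- 0L; n_bins_total <- 0L
  for (rep in 1:15) {
    cfg <- suppression_config(center_reduction = 0, rebound_amplitude = 0,
                              n_units_per_distance = 60,
                              n_fs_per_distance = 0, distances_mm = 0,
                              n_trials = 25, stim_duration_s = 1,
                              seed = 100 + rep)
    ds <- simulate_suppression_dataset(
      cfg, photostim_protocol(duration_s = 1, ramp_ms = 0))
    base <- optospread:::unit_window_rates(ds, c(-0.5, 0))
    ps <- compute_psth(ds, bin_ms = 10, window = c(0, 1000))
    for (j in seq_len(ncol(ps$unit_rate_hz))) {
      d <- ps$unit_rate_hz[, j] - base
      if (stats::sd(d) == 0) next
      p <- stats::t.test(d)$p.value
      n_sig <- n_sig + (p < 0.05)
      n_bins_total <- n_bins_total + 1L
    }
  }
  rate <- n_sig / n_bins_total
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("half-max radius matches closed forms", {
  # Gaussian reduction, 90% at center, sigma 0.68 mm
  r <- seq(0, 2.5, by = 0.01)
  prof <- exact_profile(r, 1 - 0.9 * exp(-r^2 / (2 * 0.68^2)))
  hm <- half_max_radius(prof, n_resamples = 0)
  expect_equal(hm$radius_mm, 0.68 * sqrt(2 * log(2)), tolerance = 0.01)
  expect_equal(hm$radius_mm, 0.8006, tolerance = 0.01)

  # linear reduction d(r) = 0.8 (1 - r/2): crossing exactly at 1 mm
  lin <- exact_profile(seq(0, 2, by = 0.25), 1 - 0.8 * (1 - seq(0, 2, 0.25) / 2))
  expect_equal(half_max_radius(lin, n_resamples = 0)$radius_mm, 1)

  # flat nonzero reduction never crosses
  flat <- exact_profile(seq(0, 2, by = 0.25), rep(0.6, 9))
  expect_error(half_max_radius(flat, n_resamples = 0), "never falls")
  # no suppression at the center
  none <- exact_profile(seq(0, 2, by = 0.25), rep(1, 9))
  expect_error(half_max_radius(none, n_resamples = 0), "d\\(0\\)|center")
})

test_that("half-max radius grows with the generative suppression width", {
  radii <- vapply(c(0.2, 0.45, 0.7, 0.95, 1.2), function(sig) {
    r <- seq(0, 4, by = 0.02)
    prof <- exact_profile(r, 1 - 0.9 * exp(-r^2 / (2 * sig^2)))
    half_max_radius(prof, n_resamples = 0)$radius_mm
  }, numeric(1))
  expect_true(all(diff(radii) > 0))
})

test_that("spatial profile tracks the generative suppression curve", {
  cfg <- suppression_config(center_reduction = 0.9, lateral_sigma_mm = 0.68,
                            onset_tau_ms = 1e-3, rebound_amplitude = 0,
                            n_units_per_distance = 12, n_fs_per_distance = 0,
                            distances_mm = seq(0, 2.4, by = 0.2),
                            n_trials = 30, seed = 14)
  ds <- simulate_suppression_dataset(
    cfg, photostim_protocol(duration_s = 1.3, ramp_ms = 0))
  prof <- spatial_profile(ds, units = "PYR", n_boot = 300, seed = 14)
  ok <- prof$n_units > 0
  for (k in which(ok)) {
    # generative truth averaged over the distances pooled into the bin
    tab <- attr(prof, "unit_rates")
    breaks <- attr(prof, "breaks_mm")
    in_bin <- tab$distance_mm >= breaks[k] & tab$distance_mm < breaks[k + 1]
    truth <- mean(1 - 0.9 * exp(-tab$distance_mm[in_bin]^2 / (2 * 0.68^2)))
    expect_lt(abs(prof$relative_rate[k] - truth),
              4 * max(prof$sem[k], 0.02))
  }
  # null suppression: all bins near 1
  cfg0 <- suppression_config(center_reduction = 0, rebound_amplitude = 0,
                             n_units_per_distance = 12, n_fs_per_distance = 0,
                             distances_mm = seq(0, 2.4, by = 0.4),
                             n_trials = 30, seed = 15)
  ds0 <- simulate_suppression_dataset(
    cfg0, photostim_protocol(duration_s = 1.3, ramp_ms = 0))
  prof0 <- spatial_profile(ds0, units = "PYR", n_boot = 100, seed = 15)
  expect_true(all(abs(prof0$relative_rate[prof0$n_units > 0] - 1) < 0.15))
  # single unit in a bin: degenerate s.e.m. flagged
  one <- spatial_profile(optospread:::filter_units(ds0, 1L), units = NULL,
                         n_boot = 50, seed = 1)
  expect_true("single-unit" %in% one$flag)
})

test_that("bootstrap_stat behaves at the edges and covers at 90%", {
  ident <- bootstrap_stat(rep(5, 20), mean, n_resamples = 200, seed = 1)
  expect_equal(ident$ci_lo, 5)
  expect_equal(ident$ci_hi, 5)
  expect_equal(ident$sem, 0)

  expect_warning(b1 <- bootstrap_stat(1:10, mean, n_resamples = 1, seed = 1),
                 "n_resamples = 1")
  expect_equal(b1$sem, 0)

  # coverage: 90% CI covers the true mean ~90% of the time
  set.seed(99)
  covered <- vapply(1:500, function(i) {
    x <- rnorm(100)
    b <- bootstrap_stat(x, mean, n_resamples = 200, ci_level = 0.90)
    b$ci_lo <= 0 && 0 <= b$ci_hi
  }, logical(1))
  expect_gte(mean(covered), 0.85)
  expect_lte(mean(covered), 0.95)
})
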