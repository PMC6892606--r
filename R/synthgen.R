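# Synthetic-data generators: bleached-nuclei volumes for the imaging stage and
# suppression-structured spike datasets for the electrophysiology stages.

#' Generate a synthetic volume of fluorescent nuclei
#'
#' Places `n` nuclei uniformly at random in a tissue volume and assigns each a
#' baseline fluorescence drawn from a lognormal distribution (mean
#' `baseline_mean`, coefficient of variation `baseline_cv`). The coordinate
#' convention matches the imaging stage: the laser center is at x = y = 0 on
#' the tissue surface, z = 0 at the pia and positive downward, so x and y span
#' `[-Lx/2, Lx/2]` and `[-Ly/2, Ly/2]` and z spans `[0, Lz]`. All units um.
#'
#' @param n number of nuclei (>= 0).
#' @param volume_dims numeric triple `(Lx, Ly, Lz)` in um, all > 0.
#' @param seed integer RNG seed (optional; current stream if `NULL`).
#' @param baseline_mean mean baseline fluorescence (arbitrary units, > 0).
#' @param baseline_cv coefficient of variation of baseline fluorescence.
#' @return A `nuclei_volume`: list with `positions` (n x 3 matrix, columns
#'   `x_um`, `y_um`, `z_um`), `baseline_fluorescence` (length n, > 0) and
#'   `volume_dims`.
#' @examples
#' vol <- make_nuclei_volume(100, c(1000, 1000, 1000), seed = 1)
#' range(vol$positions[, "z_um"])
#' @export
make_nuclei_volume <- function(n, volume_dims, seed = NULL,
                               baseline_mean = 100, baseline_cv = 0.2) {
  check_scalar(n, "n", lower = 0)
  if (n != round(n)) stop("`n` must be an integer count", call. = FALSE)
  if (!is.numeric(volume_dims) || length(volume_dims) != 3L ||
      any(!is.finite(volume_dims)) || any(volume_dims <= 0))
    stop("`volume_dims` must be three positive lengths (um)", call. = FALSE)
  check_scalar(baseline_mean, "baseline_mean", lower = 0, strict_lower = TRUE)
  check_scalar(baseline_cv, "baseline_cv", lower = 0)
  with_seed(seed, {
    pos <- cbind(
      x_um = stats::runif(n, -volume_dims[1] / 2, volume_dims[1] / 2),
      y_um = stats::runif(n, -volume_dims[2] / 2, volume_dims[2] / 2),
      z_um = stats::runif(n, 0, volume_dims[3])
    )
    sdlog <- sqrt(log(1 + baseline_cv^2))
    f0 <- stats::rlnorm(n, meanlog = log(baseline_mean) - sdlog^2 / 2,
                        sdlog = sdlog)
    structure(list(positions = pos, baseline_fluorescence = f0,
                   volume_dims = as.numeric(volume_dims)),
              class = "nuclei_volume")
  })
}

#' @export
print.nuclei_volume <- function(x, ...) {
  cat(sprintf("Nuclei volume: %d nuclei in %g x %g x %g um\n",
              nrow(x$positions), x$volume_dims[1], x$volume_dims[2],
              x$volume_dims[3]))
  invisible(x)
}

# evaluate relative light intensity (in [0,1]) at nucleus positions;
# `light` is either a function(x, y, z) or a light_field grid object
eval_light_at <- function(light, pos) {
  if (is.function(light)) {
    val <- light(pos[, 1L], pos[, 2L], pos[, 3L])
  } else if (inherits(light, "light_field")) {
    val <- light_field_lookup(light, pos)
  } else {
    stop("`light_field` must be a function(x, y, z) or a light_field object",
         call. = FALSE)
  }
  if (any(!is.finite(val)) || any(val < 0) || any(val > 1))
    stop("light intensity values must lie in [0, 1]", call. = FALSE)
  val
}

#' Forward-simulate photobleaching of a nuclei volume
#'
#' Applies the exponential dose model of photobleaching: each nucleus's
#' fluorescence is multiplied by `exp(-k * I * T)` where `I` is the local
#' relative light intensity (in `[0, 1]`) and `T` the light dose, then by
#' multiplicative lognormal noise with coefficient of variation `noise_cv`.
#'
#' @param volume a `nuclei_volume`.
#' @param light_field relative light intensity: either a function
#'   `f(x_um, y_um, z_um)` returning values in `[0, 1]`, or a `light_field`
#'   grid object.
#' @param k_dose bleach constant per (mW min), > 0.
#' @param dose light dose (mW min), >= 0.
#' @param noise_cv coefficient of variation of multiplicative measurement
#'   noise (0 disables noise).
#' @param seed integer RNG seed (optional).
#' @param wavelength_nm recorded in the table metadata.
#' @return An `roi_table`: data frame with columns `x_um`, `y_um`, `z_um`,
#'   `F`, with attributes `dose_mw_min` and `wavelength_nm`.
#' @examples
#' vol <- make_nuclei_volume(50, c(500, 500, 500), seed = 1)
#' rois <- bleach_forward(vol, function(x, y, z) exp(-z / 200),
#'                        k_dose = 0.015, dose = 200)
#' @export
bleach_forward <- function(volume, light_field, k_dose, dose,
                           noise_cv = 0, seed = NULL, wavelength_nm = 473) {
  stopifnot(inherits(volume, "nuclei_volume"))
  check_scalar(k_dose, "k_dose", lower = 0, strict_lower = TRUE)
  check_scalar(dose, "dose", lower = 0)
  check_scalar(noise_cv, "noise_cv", lower = 0)
  pos <- volume$positions
  intensity <- eval_light_at(light_field, pos)
  f_bleached <- volume$baseline_fluorescence * exp(-k_dose * intensity * dose)
  if (noise_cv > 0) {
    f_bleached <- with_seed(seed, {
      sdlog <- sqrt(log(1 + noise_cv^2))
      f_bleached * stats::rlnorm(length(f_bleached), -sdlog^2 / 2, sdlog)
    })
  }
  roi_table(data.frame(x_um = pos[, 1L], y_um = pos[, 2L], z_um = pos[, 3L],
                       F = f_bleached),
            dose_mw_min = dose, wavelength_nm = wavelength_nm)
}

#' Suppression configuration for the spike-dataset generator
#'
#' Parametric description of the spatial and temporal structure of optogenetic
#' suppression that [simulate_suppression_dataset()] turns into spike trains.
#' Defaults emulate a potent direct-photoinhibition experiment: 90% spike-rate
#' reduction at the laser center with a Gaussian lateral profile of sigma
#' 0.68 mm, 8 ms onset kinetics, and a modest offset rebound. Baseline rates
#' are gamma-distributed across units (shape 4) around the configured means;
#' per-cell-type baseline means (pyramidal 8 Hz, fast-spiking 15 Hz) are
#' conventions, not measurements.
#'
#' @param baseline_rate_hz mean pyramidal baseline rate (Hz).
#' @param fs_baseline_rate_hz mean fast-spiking baseline rate (Hz).
#' @param center_reduction fractional rate reduction at the laser center,
#'   in `[0, 1]`.
#' @param lateral_sigma_mm Gaussian sigma of the lateral suppression profile.
#' @param onset_tau_ms exponential time constant of suppression onset (ms).
#' @param rebound_amplitude post-offset rate elevation, fraction of baseline.
#' @param rebound_tau_ms decay time constant of the rebound (ms).
#' @param fs_activation_gain multiplicative gain of fast-spiking activation at
#'   the laser center (FS rate rises toward
#'   `baseline * (1 + gain * center_reduction * profile(r))`).
#' @param n_units_per_distance pyramidal units simulated at each distance.
#' @param n_fs_per_distance fast-spiking units at each distance.
#' @param distances_mm lateral distances of the simulated recording sites.
#' @param n_trials trials per unit.
#' @param stim_duration_s photostimulus duration (s).
#' @param baseline_window_s pre-stimulus epoch simulated per trial (s).
#' @param post_window_s post-offset epoch simulated per trial (s).
#' @param rate_shape gamma shape of across-unit baseline-rate variability.
#' @param seed integer RNG seed used by the generator.
#' @return A `suppression_config` (validated named list).
#' @export
suppression_config <- function(baseline_rate_hz = 8,
                               fs_baseline_rate_hz = 15,
                               center_reduction = 0.9,
                               lateral_sigma_mm = 0.68,
                               onset_tau_ms = 8,
                               rebound_amplitude = 0.2,
                               rebound_tau_ms = 200,
                               fs_activation_gain = 2,
                               n_units_per_distance = 20,
                               n_fs_per_distance = 4,
                               distances_mm = seq(0, 2.5, by = 0.1),
                               n_trials = 50,
                               stim_duration_s = 1.3,
                               baseline_window_s = 0.5,
                               post_window_s = 0.7,
                               rate_shape = 4,
                               seed = 1) {
  check_scalar(baseline_rate_hz, "baseline_rate_hz", lower = 0)
  check_scalar(fs_baseline_rate_hz, "fs_baseline_rate_hz", lower = 0)
  check_scalar(center_reduction, "center_reduction", lower = 0, upper = 1)
  check_scalar(lateral_sigma_mm, "lateral_sigma_mm", lower = 0, strict_lower = TRUE)
  check_scalar(onset_tau_ms, "onset_tau_ms", lower = 0, strict_lower = TRUE)
  check_scalar(rebound_amplitude, "rebound_amplitude", lower = 0)
  check_scalar(rebound_tau_ms, "rebound_tau_ms", lower = 0, strict_lower = TRUE)
  check_scalar(fs_activation_gain, "fs_activation_gain", lower = 0)
  check_scalar(n_units_per_distance, "n_units_per_distance", lower = 0)
  check_scalar(n_fs_per_distance, "n_fs_per_distance", lower = 0)
  stopifnot(is.numeric(distances_mm), all(distances_mm >= 0))
  check_scalar(n_trials, "n_trials", lower = 1)
  check_scalar(stim_duration_s, "stim_duration_s", lower = 0, strict_lower = TRUE)
  check_scalar(baseline_window_s, "baseline_window_s", lower = 0, strict_lower = TRUE)
  check_scalar(post_window_s, "post_window_s", lower = 0)
  check_scalar(rate_shape, "rate_shape", lower = 0, strict_lower = TRUE)
  structure(as.list(environment()), class = "suppression_config")
}

# lateral suppression depth at distance r (mm): fraction of baseline removed
suppression_profile <- function(config, r_mm) {
  config$center_reduction * exp(-r_mm^2 / (2 * config$lateral_sigma_mm^2))
}

# rate trajectory (Hz) of one unit; t in seconds relative to stimulus onset
unit_rate_fn <- function(config, baseline_hz, r_mm, is_fs) {
  depth <- suppression_profile(config, r_mm)
  tau_on <- config$onset_tau_ms / 1000
  tau_reb <- config$rebound_tau_ms / 1000
  dur <- config$stim_duration_s
  if (is_fs) {
    gain <- config$fs_activation_gain * depth
    function(t) {
      r <- rep(baseline_hz, length(t))
      stim <- t >= 0 & t < dur
      r[stim] <- baseline_hz * (1 + gain * (1 - exp(-t[stim] / tau_on)))
      post <- t >= dur
      r[post] <- baseline_hz * (1 + gain * exp(-(t[post] - dur) / tau_on))
      r
    }
  } else {
    target <- 1 - depth
    reb <- config$rebound_amplitude
    function(t) {
      r <- rep(baseline_hz, length(t))
      stim <- t >= 0 & t < dur
      r[stim] <- baseline_hz * (target + (1 - target) * exp(-t[stim] / tau_on))
      post <- t >= dur
      r[post] <- baseline_hz * (1 + reb * exp(-(t[post] - dur) / tau_reb))
      r
    }
  }
}

#' Simulate a suppression-structured spike dataset
#'
#' Generates pyramidal and fast-spiking units at the configured lateral
#' distances and draws their spikes as inhomogeneous Poisson processes from
#' parametric rate trajectories: pyramidal rates decay exponentially (time
#' constant `onset_tau_ms`) from baseline toward
#' `baseline * (1 - center_reduction * exp(-r^2 / (2 * lateral_sigma_mm^2)))`
#' during the stimulus and show an exponential rebound above baseline after
#' offset; fast-spiking units are driven up by a mirrored activation profile
#' scaled by `fs_activation_gain`. Mean spike waveforms are synthesized so
#' that fast-spiking trough-to-peak widths fall below 0.35 ms and pyramidal
#' widths above 0.45 ms. Spike times are stored relative to stimulus onset;
#' each trial spans `[-baseline_window_s, stim_duration_s + post_window_s]`.
#'
#' @param config a [suppression_config()].
#' @param protocol a [photostim_protocol()]; its duration overrides
#'   `config$stim_duration_s` when supplied.
#' @return A `spike_dataset` (see [spike_dataset()]), with the generating
#'   ground truth (`class_true`, `distance_mm`, per-unit baseline rate) in the
#'   units table and the config echoed in `metadata`.
#' @seealso [sample_inhomogeneous_poisson()], [classify_units()]
#' @export
simulate_suppression_dataset <- function(config = suppression_config(),
                                         protocol = photostim_protocol()) {
  stopifnot(inherits(config, "suppression_config"))
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "photostim_protocol"))
    config$stim_duration_s <- protocol$duration_s
  }
  with_seed(config$seed, {
    grid <- expand.grid(distance_mm = config$distances_mm,
                        slot = seq_len(config$n_units_per_distance +
                                         config$n_fs_per_distance))
    is_fs <- grid$slot > config$n_units_per_distance
    n_units <- nrow(grid)
    base_mean <- ifelse(is_fs, config$fs_baseline_rate_hz,
                        config$baseline_rate_hz)
    baseline <- stats::rgamma(n_units, shape = config$rate_shape,
                              rate = config$rate_shape / base_mean)
    width_ms <- ifelse(is_fs, stats::runif(n_units, 0.20, 0.32),
                       stats::runif(n_units, 0.50, 0.70))

    t0 <- -config$baseline_window_s
    t1 <- config$stim_duration_s + config$post_window_s
    spikes <- vector("list", n_units)
    waveforms <- matrix(NA_real_, nrow = n_units, ncol = 64)
    for (u in seq_len(n_units)) {
      fn <- unit_rate_fn(config, baseline[u], grid$distance_mm[u], is_fs[u])
      tr <- sample_inhomogeneous_poisson(fn, duration_s = t1 - t0,
                                         n_trials = config$n_trials,
                                         t_start = t0)
      spikes[[u]] <- data.frame(
        unit_id = u,
        trial_id = rep(seq_along(tr), vapply(tr, length, 1L)),
        spike_time_s = unlist(tr)
      )
      waveforms[u, ] <- synth_waveform(width_ms[u])
    }
    units <- data.frame(
      unit_id = seq_len(n_units),
      class_true = ifelse(is_fs, "FS", "PYR"),
      lateral_distance_um = grid$distance_mm * 1000,
      depth_um = stats::runif(n_units, 100, 900),
      width_ms = width_ms,
      baseline_rate_true_hz = baseline
    )
    trials <- data.frame(trial_id = seq_len(config$n_trials),
                         condition_id = "cond1")
    conditions <- list(cond1 = if (is.null(protocol)) {
      photostim_protocol(duration_s = config$stim_duration_s)
    } else protocol)
    spike_dataset(
      units = units,
      spikes = do.call(rbind, spikes),
      trials = trials,
      conditions = conditions,
      waveforms = waveforms,
      sampling_rate_hz = 19531.25,
      metadata = list(seed = config$seed,
                      trial_window_s = c(t0, t1),
                      config = unclass(config))
    )
  })
}

# biphasic mean waveform with trough-to-peak width `width_ms`; 64 samples at
# 19531.25 Hz, trough fixed at sample 20
synth_waveform <- function(width_ms, sampling_rate_hz = 19531.25,
                           n_samples = 64L, trough_at = 20L) {
  dt_ms <- 1000 / sampling_rate_hz
  peak_at <- trough_at + round(width_ms / dt_ms)
  i <- seq_len(n_samples)
  w <- -exp(-(i - trough_at)^2 / (2 * (width_ms / dt_ms / 4)^2)) +
    0.45 * exp(-(i - peak_at)^2 / (2 * (width_ms / dt_ms / 3)^2))
  w
}

#' Draw spike trains from an inhomogeneous Poisson process
#'
#' Thinning (Lewis-Shedler) sampler: candidate events are drawn from a
#' homogeneous Poisson process at the rate bound and retained with probability
#' `rate_fn(t) / bound`. A 1 ms absolute refractory period is imposed by
#' deleting spikes closer than 1 ms to their predecessor.
#'
#' @param rate_fn vectorized function mapping time (s) to rate (Hz); must be
#'   nonnegative and bounded.
#' @param duration_s trial duration (s).
#' @param n_trials number of independent trials.
#' @param seed integer RNG seed (optional).
#' @param t_start trial start time (s); `rate_fn` is evaluated on
#'   `[t_start, t_start + duration_s]`.
#' @param rate_max upper bound on the rate (Hz); estimated from a dense grid
#'   when `NULL`.
#' @param refractory_ms absolute refractory period (ms); 0 disables it.
#' @return A list of `n_trials` sorted numeric vectors of spike times (s).
#' @examples
#' trains <- sample_inhomogeneous_poisson(function(t) 10 + 0 * t, 1, 5, seed = 1)
#' @export
sample_inhomogeneous_poisson <- function(rate_fn, duration_s, n_trials,
                                         seed = NULL, t_start = 0,
                                         rate_max = NULL, refractory_ms = 1) {
  check_scalar(duration_s, "duration_s", lower = 0)
  check_scalar(n_trials, "n_trials", lower = 1)
  with_seed(seed, {
    grid <- seq(t_start, t_start + duration_s, length.out = 512L)
    r_grid <- rate_fn(grid)
    if (any(!is.finite(r_grid)) || any(r_grid < 0))
      stop("rate_fn must be nonnegative and finite", call. = FALSE)
    if (is.null(rate_max)) rate_max <- max(r_grid) * 1.05
    out <- vector("list", n_trials)
    if (rate_max <= 0) {
      for (k in seq_len(n_trials)) out[[k]] <- numeric(0)
      return(out)
    }
    for (k in seq_len(n_trials)) {
      n_cand <- stats::rpois(1L, rate_max * duration_s)
      cand <- sort(stats::runif(n_cand, t_start, t_start + duration_s))
      r_cand <- rate_fn(cand)
      if (any(r_cand < 0)) stop("rate_fn returned a negative rate", call. = FALSE)
      if (any(r_cand > rate_max * (1 + 1e-8)))
        stop("rate_fn exceeds the supplied rate bound", call. = FALSE)
      keep <- stats::runif(n_cand) < r_cand / rate_max
      st <- cand[keep]
      if (refractory_ms > 0 && length(st) > 1L) {
        refr <- refractory_ms / 1000
        ok <- logical(length(st)); ok[1L] <- TRUE; last <- st[1L]
        for (j in 2L:length(st)) {
          if (st[j] - last >= refr) { ok[j] <- TRUE; last <- st[j] }
        }
        st <- st[ok]
      }
      out[[k]] <- st
    }
    out
  })
}
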