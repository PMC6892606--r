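# Shared fixtures, all generated in code.

# small two-unit dataset with hand-countable spikes
tiny_dataset <- function(stim_rates = c(0, 2), base_rates = c(10, 2),
                         n_trials = 1, duration_s = 1,
                         distances_um = NULL) {
  # base_rates * 0.5 and stim_rates * duration_s must be whole spike counts
  n_units <- length(stim_rates)
  if (is.null(distances_um)) distances_um <- rep(0, n_units)
  spikes <- do.call(rbind, lapply(seq_len(n_units), function(u) {
    st <- c()
    for (tr in seq_len(n_trials)) {
      pre <- if (base_rates[u] > 0)
        seq(-0.5, -1e-3, length.out = round(base_rates[u] * 0.5)) else numeric(0)
      dur <- if (stim_rates[u] > 0)
        seq(1e-3, duration_s - 1e-3,
            length.out = round(stim_rates[u] * duration_s)) else numeric(0)
      st <- rbind(st, if (length(c(pre, dur)))
        data.frame(unit_id = u, trial_id = tr, spike_time_s = c(pre, dur)))
    }
    st
  }))
  if (is.null(spikes))
    spikes <- data.frame(unit_id = integer(0), trial_id = integer(0),
                         spike_time_s = numeric(0))
  spike_dataset(
    units = data.frame(unit_id = seq_len(n_units),
                       lateral_distance_um = distances_um,
                       depth_um = 400),
    spikes = spikes,
    trials = data.frame(trial_id = seq_len(n_trials), condition_id = "c1"),
    conditions = list(c1 = photostim_protocol(duration_s = duration_s,
                                              ramp_ms = 0)),
    metadata = list(trial_window_s = c(-0.5, duration_s + 0.5)))
}

# spatial_profile object built from exact relative rates (no spikes), for
# closed-form half-max checks
exact_profile <- function(distance_mm, relative_rate) {
  structure(data.frame(distance_mm = distance_mm,
                       relative_rate = relative_rate,
                       n_units = 1L, sem = 0, flag = ""),
            class = c("spatial_profile", "data.frame"))
}

# separable light field evaluated analytically
gauss_exp_field <- function(z_efold_um, lateral_sigma_um) {
  function(x, y, z) exp(-z / z_efold_um) *
    exp(-(x^2 + y^2) / (2 * lateral_sigma_um^2))
}

# closed-form 2x2 rectified-linear fixed point in the fully active branch:
# solves (I - W) r = h for W = [[wee, -wei], [wie, -wii]]
solve_2x2_fixed_point <- function(wee, wei, wie, wii, he, hi) {
  A <- matrix(c(1 - wee, wei, -wie, 1 + wii), 2, 2, byrow = TRUE)
  as.numeric(solve(A, c(he, hi)))
}
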