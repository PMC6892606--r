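# Rate-based excitatory-inhibitory network with rectified-linear transfer,
# optionally spatially extended on a 1-D lateral grid. The model generates
# datasets exhibiting the paradoxical effect of inhibition-stabilized
# networks (ISN): when the excitatory subnetwork is unstable alone
# (w_ee > 1 in the unit-gain convention), extra drive to the inhibitory
# population *lowers* its steady-state rate in the fully active branch
# (d r_I / d h_I = (1 - w_ee) / det(I - W) < 0).

#' Parameters of the E-I rate network
#'
#' Dynamics: `tau * dr/dt = -r + [W r + h + opsin drive]_+` with
#' rectified-linear transfer of unit gain and effective weight matrix
#' `W = [[w_ee, -w_ei], [w_ie, -w_ii]]`. The optional `spatial` component
#' places the two populations on a 1-D lateral grid with Gaussian coupling
#' kernels, row-normalized so each kernel's row sums equal the scalar weight.
#'
#' @param w_ee,w_ei,w_ie,w_ii nonnegative coupling magnitudes (E<-E, E<-I,
#'   I<-E, I<-I).
#' @param tau_e_ms,tau_i_ms population time constants (ms), > 0.
#' @param h_e,h_i baseline external drives.
#' @param opsin_gain drive added per unit relative light intensity.
#' @param target_population `"I"` (ChR-assisted photoinhibition) or `"E"`
#'   (direct photoinhibition, use a negative `opsin_gain`).
#' @param spatial optional list: `grid_spacing_um`, `extent_um`, and kernel
#'   widths `sigma_ee_um`, `sigma_ei_um`, `sigma_ie_um`, `sigma_ii_um`
#'   (all > 0).
#' @return An `isn_params`.
#' @examples
#' isn_params(w_ee = 2, w_ei = 2.5, w_ie = 3, w_ii = 2, h_e = 1, h_i = 0)
#' @export
isn_params <- function(w_ee = 2, w_ei = 2.5, w_ie = 3, w_ii = 2,
                       tau_e_ms = 10, tau_i_ms = 5,
                       h_e = 1, h_i = 0,
                       opsin_gain = 1,
                       target_population = c("I", "E"),
                       spatial = NULL) {
  target_population <- match.arg(target_population)
  for (nm in c("w_ee", "w_ei", "w_ie", "w_ii"))
    check_scalar(get(nm), nm, lower = 0)
  check_scalar(tau_e_ms, "tau_e_ms", lower = 0, strict_lower = TRUE)
  check_scalar(tau_i_ms, "tau_i_ms", lower = 0, strict_lower = TRUE)
  check_scalar(h_e, "h_e"); check_scalar(h_i, "h_i")
  check_scalar(opsin_gain, "opsin_gain")
  if (!is.null(spatial)) {
    for (nm in c("grid_spacing_um", "extent_um", "sigma_ee_um",
                 "sigma_ei_um", "sigma_ie_um", "sigma_ii_um"))
      check_scalar(spatial[[nm]], paste0("spatial$", nm),
                   lower = 0, strict_lower = TRUE)
  }
  structure(list(w_ee = w_ee, w_ei = w_ei, w_ie = w_ie, w_ii = w_ii,
                 tau_e_ms = tau_e_ms, tau_i_ms = tau_i_ms,
                 h_e = h_e, h_i = h_i, opsin_gain = opsin_gain,
                 target_population = target_population, spatial = spatial),
            class = "isn_params")
}

#' @export
print.isn_params <- function(x, ...) {
  cat(sprintf("ISN params: w_ee=%g w_ei=%g w_ie=%g w_ii=%g, tau=(%g, %g) ms, h=(%g, %g)\n",
              x$w_ee, x$w_ei, x$w_ie, x$w_ii, x$tau_e_ms, x$tau_i_ms,
              x$h_e, x$h_i))
  cat(sprintf("  opsin: gain %g on %s population%s\n", x$opsin_gain,
              x$target_population,
              if (is.null(x$spatial)) "" else sprintf(
                "; spatial grid, %g um spacing", x$spatial$grid_spacing_um)))
  invisible(x)
}

# lateral grid node positions (um), centered on the beam axis
isn_grid <- function(params) {
  sp <- params$spatial
  if (is.null(sp)) return(0)
  half <- floor(sp$extent_um / 2 / sp$grid_spacing_um)
  seq(-half, half) * sp$grid_spacing_um
}

# row-normalized Gaussian coupling kernel; row sums equal `weight`.
# sigma -> 0 relative to spacing degenerates to the identity * weight.
gauss_kernel <- function(pos, sigma_um, weight) {
  d2 <- outer(pos, pos, function(a, b) (a - b)^2)
  k <- exp(-d2 / (2 * sigma_um^2))
  k * (weight / rowSums(k))
}

# assemble the full (signed) weight matrix and input vector builder
isn_system <- function(params, light) {
  pos <- isn_grid(params)
  n <- length(pos)
  if (n == 1L) {
    W <- matrix(c(params$w_ee, -params$w_ei,
                  params$w_ie, -params$w_ii), 2L, 2L, byrow = TRUE)
    h <- c(params$h_e, params$h_i)
    light_vec <- if (length(light) == 1L) light else
      stop("scalar light required for the non-spatial model", call. = FALSE)
    drive <- rep(0, 2L)
    drive[if (params$target_population == "E") 1L else 2L] <-
      params$opsin_gain * light_vec
    tau <- c(params$tau_e_ms, params$tau_i_ms)
  } else {
    sp <- params$spatial
    Kee <- gauss_kernel(pos, sp$sigma_ee_um, params$w_ee)
    Kei <- gauss_kernel(pos, sp$sigma_ei_um, params$w_ei)
    Kie <- gauss_kernel(pos, sp$sigma_ie_um, params$w_ie)
    Kii <- gauss_kernel(pos, sp$sigma_ii_um, params$w_ii)
    W <- rbind(cbind(Kee, -Kei), cbind(Kie, -Kii))
    h <- c(rep(params$h_e, n), rep(params$h_i, n))
    light_vec <- if (length(light) == 1L) rep(light, n) else {
      if (length(light) != n)
        stop("light field length must match the spatial grid (", n,
             " nodes)", call. = FALSE)
      light
    }
    drive <- numeric(2L * n)
    sel <- if (params$target_population == "E") seq_len(n) else n + seq_len(n)
    drive[sel] <- params$opsin_gain * light_vec
    tau <- c(rep(params$tau_e_ms, n), rep(params$tau_i_ms, n))
  }
  list(W = W, h = h, drive = drive, tau = tau, n_nodes = n, pos = pos)
}

#' Steady state of the E-I rate network under opsin drive
#'
#' Finds the fixed point of `tau dr/dt = -r + [W r + h + drive]_+` by
#' relaxed iteration (explicit Euler with step `tau_min / 20`), declaring
#' convergence at `max |delta r| < 1e-10`. The stability flag reports whether
#' all Jacobian eigenvalues in the active linear branch have negative real
#' part.
#'
#' @param params an [isn_params()].
#' @param light relative light intensity: scalar, or per-node vector in
#'   spatial mode.
#' @param r0 optional initial rates.
#' @param max_iter iteration cap (default 1e5) before a non-convergence
#'   error naming the parameter set.
#' @return An `isn_fixed_point`: `rates` (named `E`/`I`, or a matrix nodes x
#'   2 in spatial mode), `stable`, `n_iter`, `eigenvalues`.
#' @examples
#' p <- isn_params(w_ee = 2, w_ei = 2.5, w_ie = 3, w_ii = 2, h_e = 1, h_i = 0)
#' isn_steady_state(p, light = 0)$rates      # (2/3, 2/3)
#' isn_steady_state(p, light = 0.45)$rates   # r_I drops: paradoxical
#' @export
isn_steady_state <- function(params, light = 0, r0 = NULL, max_iter = 1e5) {
  stopifnot(inherits(params, "isn_params"))
  sys <- isn_system(params, light)
  m <- length(sys$h)
  r <- if (is.null(r0)) pmax(sys$h + sys$drive, 0) else rep_len(r0, m)
  dt <- min(sys$tau) / 20
  step <- dt / sys$tau
  input <- sys$h + sys$drive
  resid <- Inf
  for (it in seq_len(max_iter)) {
    target <- as.numeric(pmax(sys$W %*% r + input, 0))
    resid <- max(abs(target - r))
    if (resid < 1e-10) break
    r <- r + step * (target - r)
    if (any(!is.finite(r)) || max(r) > 1e9)
      stop(sprintf(
        "rates diverged during fixed-point iteration (w_ee=%g w_ei=%g w_ie=%g w_ii=%g, light=%g)",
        params$w_ee, params$w_ei, params$w_ie, params$w_ii, light[1L]),
        call. = FALSE)
  }
  if (resid >= 1e-10)
    stop(sprintf(
      "fixed-point iteration did not converge in %g iterations (w_ee=%g w_ei=%g w_ie=%g w_ii=%g, light=%g)",
      max_iter, params$w_ee, params$w_ei, params$w_ie, params$w_ii,
      light[1L]), call. = FALSE)
  active <- as.numeric(sys$W %*% r + input) > 0
  # rectifier derivative gates row i (the input to unit i)
  jac <- sweep(-diag(m) + sys$W * as.numeric(active), 1L, sys$tau, "/")
  ev <- eigen(jac, only.values = TRUE)$values
  rates <- if (sys$n_nodes == 1L) c(E = r[1L], I = r[2L]) else
    matrix(r, ncol = 2L, dimnames = list(NULL, c("E", "I")))
  structure(list(rates = rates, stable = all(Re(ev) < 0), n_iter = it,
                 eigenvalues = ev, pos_um = sys$pos),
            class = "isn_fixed_point")
}

#' @export
print.isn_fixed_point <- function(x, ...) {
  if (is.matrix(x$rates)) {
    cat(sprintf("ISN fixed point on %d nodes (%s)\n", nrow(x$rates),
                if (x$stable) "stable" else "UNSTABLE"))
  } else {
    cat(sprintf("ISN fixed point: r_E = %.4f, r_I = %.4f (%s, %d iterations)\n",
                x$rates["E"], x$rates["I"],
                if (x$stable) "stable" else "UNSTABLE", x$n_iter))
  }
  invisible(x)
}

#' Simulate E-I rate dynamics under a photostimulus
#'
#' Explicit-Euler integration of the rectified-linear rate dynamics. With
#' constant light the trajectory converges to the [isn_steady_state()] fixed
#' point; with `protocol$temporal_profile = "sinusoid_40hz"` the opsin drive
#' is multiplied by a 40 Hz raised-cosine waveform of unit mean (so reported
#' power remains the time average), with the protocol's terminal linear ramp
#' applied.
#'
#' @param params an [isn_params()].
#' @param protocol a [photostim_protocol()] (or `NULL` for constant light
#'   over the whole run).
#' @param light relative light intensity (scalar or per-node vector).
#' @param duration_s simulated time (s); defaults to the protocol duration
#'   plus 0.5 s lead-in and tail.
#' @param dt_ms integration step; must be at most `min(tau)/10`, default
#'   `min(tau)/20`.
#' @param rate_ceiling error threshold for runaway rates.
#' @return A `rate_trajectory`: `time_ms`, `rates` (time x populations; in
#'   spatial mode columns are E nodes then I nodes), `pos_um`.
#' @export
isn_simulate <- function(params, protocol = NULL, light = 1,
                         duration_s = NULL, dt_ms = NULL,
                         rate_ceiling = 1e6) {
  stopifnot(inherits(params, "isn_params"))
  sys <- isn_system(params, light)
  tau_min <- min(sys$tau)
  if (is.null(dt_ms)) dt_ms <- tau_min / 20
  if (dt_ms > tau_min / 10)
    stop(sprintf("dt_ms must be <= min(tau)/10 = %g ms", tau_min / 10),
         call. = FALSE)
  stim_on <- 0
  stim_off <- if (is.null(protocol)) Inf else protocol$duration_s * 1000
  if (is.null(duration_s))
    duration_s <- if (is.null(protocol)) 1 else protocol$duration_s + 1
  t_ms <- seq(-500, duration_s * 1000 - 500, by = dt_ms)
  m <- length(sys$h)
  out <- matrix(NA_real_, nrow = length(t_ms), ncol = m)
  base <- isn_steady_state(params, light = if (length(light) == 1L) 0 else
    rep(0, length(light)))
  r <- if (is.matrix(base$rates)) as.numeric(base$rates) else
    as.numeric(base$rates)
  step <- dt_ms / sys$tau
  for (i in seq_along(t_ms)) {
    t <- t_ms[i]
    mod <- if (t < stim_on || t >= stim_off) 0 else {
      m40 <- if (!is.null(protocol) &&
                 protocol$temporal_profile == "sinusoid_40hz")
        1 - cos(2 * pi * 40 * t / 1000) else 1
      ramp <- if (!is.null(protocol) && protocol$ramp_ms > 0 &&
                  t > stim_off - protocol$ramp_ms)
        (stim_off - t) / protocol$ramp_ms else 1
      m40 * ramp
    }
    target <- pmax(sys$W %*% r + sys$h + mod * sys$drive, 0)
    r <- r + step * (as.numeric(target) - r)
    if (any(r > rate_ceiling))
      stop(sprintf(
        "rate exceeded ceiling %g at t = %.1f ms: unstable parameter set (w_ee=%g, w_ii=%g)",
        rate_ceiling, t, params$w_ee, params$w_ii), call. = FALSE)
    out[i, ] <- r
  }
  cols <- if (sys$n_nodes == 1L) c("E", "I") else
    c(paste0("E", seq_len(sys$n_nodes)), paste0("I", seq_len(sys$n_nodes)))
  colnames(out) <- cols
  structure(list(time_ms = t_ms, rates = out, pos_um = sys$pos,
                 dt_ms = dt_ms, n_nodes = sys$n_nodes),
            class = "rate_trajectory")
}

#' @export
print.rate_trajectory <- function(x, ...) {
  cat(sprintf("Rate trajectory: %d steps of %g ms, %d node(s)\n",
              length(x$time_ms), x$dt_ms, x$n_nodes))
  invisible(x)
}

#' @export
plot.rate_trajectory <- function(x, populations = c("E", "I"), ...) {
  sel <- if (x$n_nodes == 1L) populations else
    c(paste0("E", ceiling(x$n_nodes / 2)), paste0("I", ceiling(x$n_nodes / 2)))
  graphics::matplot(x$time_ms, x$rates[, sel, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (ms)", ylab = "rate", ...)
  graphics::legend("topright", legend = sel, lty = 1,
                   col = seq_along(sel), bty = "n")
  invisible(x)
}

#' Simulate a paradoxical-effect spike dataset from the ISN model
#'
#' For each light intensity, the network steady state under opsin drive to
#' the target population sets per-class firing rates (E = pyramidal,
#' I = fast-spiking); Poisson spike datasets are then generated at those
#' rates, one dataset per intensity, for [paradoxical_scan()].
#'
#' @param params an [isn_params()].
#' @param intensities vector of relative light intensities.
#' @param n_pyr,n_fs units per class.
#' @param rate_scale_hz firing rate corresponding to one model rate unit.
#' @param n_trials,duration_s trials and stimulus duration per dataset.
#' @param seed integer RNG seed.
#' @return List with `datasets` (one `spike_dataset` per intensity),
#'   `intensities`, and `rates` (the model E/I steady-state rates).
#' @export
simulate_isn_datasets <- function(params, intensities,
                                  n_pyr = 40, n_fs = 10,
                                  rate_scale_hz = 10,
                                  n_trials = 20, duration_s = 1,
                                  seed = 1) {
  stopifnot(inherits(params, "isn_params"))
  rates <- t(vapply(intensities, function(L)
    isn_steady_state(params, light = L)$rates, numeric(2)))
  colnames(rates) <- c("E", "I")
  base <- isn_steady_state(params, light = 0)$rates
  protocol <- photostim_protocol(duration_s = duration_s, ramp_ms = 0,
                                 temporal_profile = "constant")
  datasets <- with_seed(seed, lapply(seq_along(intensities), function(k) {
    make_two_rate_dataset(
      base_e_hz = base["E"] * rate_scale_hz,
      base_i_hz = base["I"] * rate_scale_hz,
      stim_e_hz = rates[k, "E"] * rate_scale_hz,
      stim_i_hz = rates[k, "I"] * rate_scale_hz,
      n_pyr = n_pyr, n_fs = n_fs, n_trials = n_trials,
      protocol = protocol)
  }))
  list(datasets = datasets, intensities = intensities, rates = rates,
       baseline = base)
}

# piecewise-constant two-class Poisson dataset (baseline then stimulus rate)
make_two_rate_dataset <- function(base_e_hz, base_i_hz, stim_e_hz, stim_i_hz,
                                  n_pyr, n_fs, n_trials, protocol) {
  dur <- protocol$duration_s
  t0 <- -0.5; t1 <- dur + 0.2
  n_units <- n_pyr + n_fs
  is_fs <- c(rep(FALSE, n_pyr), rep(TRUE, n_fs))
  spikes <- vector("list", n_units)
  width_ms <- ifelse(is_fs, stats::runif(n_units, 0.20, 0.32),
                     stats::runif(n_units, 0.50, 0.70))
  for (u in seq_len(n_units)) {
    b <- if (is_fs[u]) base_i_hz else base_e_hz
    s <- if (is_fs[u]) stim_i_hz else stim_e_hz
    fn <- function(t) ifelse(t >= 0 & t < dur, s, b)
    tr <- sample_inhomogeneous_poisson(fn, duration_s = t1 - t0,
                                       n_trials = n_trials, t_start = t0)
    spikes[[u]] <- data.frame(unit_id = u,
                              trial_id = rep(seq_along(tr),
                                             vapply(tr, length, 1L)),
                              spike_time_s = unlist(tr))
  }
  units <- data.frame(unit_id = seq_len(n_units),
                      class_true = ifelse(is_fs, "FS", "PYR"),
                      class_label = ifelse(is_fs, "FS", "PYR"),
                      lateral_distance_um = 0,
                      depth_um = 500,
                      width_ms = width_ms)
  spike_dataset(units = units,
                spikes = do.call(rbind, spikes),
                trials = data.frame(trial_id = seq_len(n_trials),
                                    condition_id = "cond1"),
                conditions = list(cond1 = protocol),
                metadata = list(trial_window_s = c(t0, t1)))
}
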