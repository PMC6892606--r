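# Spatial suppression profiles, half-max radius, and bootstrap machinery.
# Uncertainty follows the resampling convention of population recordings:
# neurons (not trials) are resampled with replacement.

#' Bootstrap a statistic over units
#'
#' Resamples units with replacement and recomputes `statistic` on each
#' resample. The standard error is the standard deviation of the resampled
#' statistics; the confidence interval is the central percentile interval.
#' Resamples on which the statistic is undefined (`NA` or error) are redrawn
#' and counted.
#'
#' @param units a vector, list or data frame of per-unit values; data frames
#'   are resampled by row.
#' @param statistic function of a resampled `units` object returning a
#'   scalar.
#' @param n_resamples number of bootstrap resamples; conventional choices are
#'   1000-10000 for standard errors and 2000 for confidence intervals.
#' @param ci_level central CI level, default 0.90.
#' @param seed integer RNG seed (optional).
#' @param max_redraw cap on redrawn degenerate resamples.
#' @return A `bootstrap_result`: `point` (statistic on the full sample),
#'   `sem`, `ci_lo`, `ci_hi`, `ci_level`, `n_resamples`, `seed`,
#'   `n_redrawn`.
#' @export
bootstrap_stat <- function(units, statistic, n_resamples = 1000,
                           ci_level = 0.90, seed = NULL, max_redraw = 100L) {
  check_scalar(n_resamples, "n_resamples", lower = 1)
  check_scalar(ci_level, "ci_level", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  n <- if (is.data.frame(units)) nrow(units) else length(units)
  if (n < 1L) stop("need at least one unit", call. = FALSE)
  take <- function(obj, idx) {
    if (is.data.frame(obj)) obj[idx, , drop = FALSE] else obj[idx]
  }
  point <- statistic(units)
  with_seed(seed, {
    stats_b <- numeric(n_resamples)
    n_redrawn <- 0L
    for (b in seq_len(n_resamples)) {
      val <- NA_real_
      for (try in seq_len(max_redraw + 1L)) {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(statistic(take(units, idx)),
                        error = function(e) NA_real_)
        if (is.finite(val)) break
        n_redrawn <- n_redrawn + 1L
      }
      stats_b[b] <- val
    }
    if (n_resamples == 1L)
      warning("n_resamples = 1: standard error reported as 0")
    sem <- if (n_resamples > 1L) stats::sd(stats_b, na.rm = TRUE) else 0
    a <- (1 - ci_level) / 2
    ci <- stats::quantile(stats_b, c(a, 1 - a), na.rm = TRUE, names = FALSE)
    structure(list(point = point, sem = sem,
                   ci_lo = ci[1L], ci_hi = ci[2L], ci_level = ci_level,
                   n_resamples = as.integer(n_resamples), seed = seed,
                   n_redrawn = n_redrawn, resamples = stats_b),
              class = "bootstrap_result")
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%.4g (s.e.m. %.3g, %g%% CI [%.4g, %.4g], %d resamples)\n",
              x$point, x$sem, 100 * x$ci_level, x$ci_lo, x$ci_hi,
              x$n_resamples))
  if (x$n_redrawn > 0)
    cat(sprintf("  %d degenerate resample(s) redrawn\n", x$n_redrawn))
  invisible(x)
}

# per-unit baseline/stimulus rates with distance, the raw material of the
# spatial profile and its bootstrap
unit_rate_table <- function(dataset, units, stim_window, base_window,
                            include_ramp) {
  ids <- select_units(dataset, units)
  if (length(ids) == 0L) stop("empty unit selection", call. = FALSE)
  ds <- filter_units(dataset, ids)
  if (is.null(stim_window)) stim_window <- default_stim_window(ds, include_ramp)
  data.frame(
    unit_id = ids,
    distance_mm = ds$units$lateral_distance_um / 1000,
    base_hz = unit_window_rates(ds, base_window),
    stim_hz = unit_window_rates(ds, stim_window)
  )
}

# bin a unit-rate table into a distance profile (population convention)
bin_profile <- function(tab, breaks) {
  bin <- cut(tab$distance_mm, breaks = breaks, right = FALSE,
             include.lowest = FALSE)
  centers <- (breaks[-length(breaks)] + breaks[-1L]) / 2
  base <- tapply(tab$base_hz, bin, mean, default = NA_real_)
  stim <- tapply(tab$stim_hz, bin, mean, default = NA_real_)
  n <- tapply(rep(1, nrow(tab)), bin, sum, default = 0)
  data.frame(distance_mm = centers,
             relative_rate = as.numeric(stim) / as.numeric(base),
             n_units = as.integer(n))
}

#' Spatial profile of relative spike rate versus lateral distance
#'
#' Bins units by lateral distance from the photostimulus center (default
#' 0.25 mm bins from 0) and computes the population relative spike rate per
#' bin, with a bootstrap standard error from resampling units within each
#' bin. Empty bins are retained with `NA` and flagged; bins holding a single
#' unit get a degenerate (zero) resampling s.e.m. and are flagged too.
#'
#' @param dataset a `spike_dataset` whose units carry `lateral_distance_um`.
#' @param units unit selection (class label such as `"PYR"`, or ids).
#' @param breaks_mm distance-bin edges (mm); default 0.25 mm bins covering
#'   the data.
#' @param n_boot bootstrap resamples for the per-bin s.e.m., default 1000.
#' @param seed integer RNG seed for the bootstrap.
#' @param stim_window,base_window,include_ramp rate windows as in
#'   [relative_rate_population()].
#' @return A `spatial_profile`: data frame with `distance_mm` (bin centers),
#'   `relative_rate`, `sem`, `n_units`, `flag`; the per-unit rate table and
#'   bin edges ride along as attributes for downstream bootstrapping.
#' @export
spatial_profile <- function(dataset, units = "PYR", breaks_mm = NULL,
                            n_boot = 1000, seed = NULL,
                            stim_window = NULL, base_window = c(-0.5, 0),
                            include_ramp = FALSE) {
  stopifnot(inherits(dataset, "spike_dataset"))
  tab <- unit_rate_table(dataset, units, stim_window, base_window,
                         include_ramp)
  if (is.null(breaks_mm))
    breaks_mm <- seq(0, ceiling(max(tab$distance_mm) / 0.25) * 0.25 + 0.25,
                     by = 0.25)
  prof <- bin_profile(tab, breaks_mm)
  bin <- cut(tab$distance_mm, breaks = breaks_mm, right = FALSE)
  sems <- rep(NA_real_, nrow(prof))
  with_seed(seed, {
    for (k in seq_len(nrow(prof))) {
      in_bin <- which(as.integer(bin) == k)
      if (length(in_bin) == 0L) next
      if (length(in_bin) == 1L) { sems[k] <- 0; next }
      sub <- tab[in_bin, ]
      reps <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(sub), nrow(sub), replace = TRUE)
        mean(sub$stim_hz[idx]) / mean(sub$base_hz[idx])
      }, numeric(1))
      sems[k] <- stats::sd(reps, na.rm = TRUE)
    }
  })
  prof$sem <- sems
  prof$flag <- ifelse(prof$n_units == 0L, "empty",
                      ifelse(prof$n_units == 1L, "single-unit", ""))
  structure(prof, class = c("spatial_profile", "data.frame"),
            unit_rates = tab, breaks_mm = breaks_mm)
}

#' @export
plot.spatial_profile <- function(x, ...) {
  ok <- is.finite(x$relative_rate)
  graphics::plot(x$distance_mm[ok], x$relative_rate[ok], type = "b",
                 ylim = c(0, max(1, x$relative_rate[ok], na.rm = TRUE)),
                 xlab = "lateral distance (mm)", ylab = "relative spike rate",
                 ...)
  graphics::arrows(x$distance_mm[ok], x$relative_rate[ok] - x$sem[ok],
                   x$distance_mm[ok], x$relative_rate[ok] + x$sem[ok],
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

# point estimate of the half-max radius from a binned profile:
# reduction d(r) = 1 - R(r); first r where d crosses d(center)/2
half_max_radius_point <- function(distance_mm, relative_rate) {
  ok <- is.finite(relative_rate)
  r <- distance_mm[ok]
  d <- 1 - relative_rate[ok]
  if (length(r) < 2L)
    stop("need at least two nonempty distance bins", call. = FALSE)
  d0 <- d[1L]
  if (d0 <= 0)
    stop("no suppression at the photostimulus center (d(0) <= 0)",
         call. = FALSE)
  cross <- first_downward_crossing(r, d, d0 / 2)
  if (is.na(cross))
    stop(sprintf(
      "suppression never falls to half its center value within %g mm; the half-max radius exceeds the measured range",
      max(r)), call. = FALSE)
  cross
}

#' Half-max radius of photoinhibition
#'
#' The lateral distance at which the spike-rate reduction
#' `d(r) = 1 - R(r)` falls to half its value at the photostimulus center
#' (innermost bin by default), located by linear interpolation between bin
#' centers, smallest crossing first. When the profile carries its per-unit
#' rate table (as [spatial_profile()] output does), a bootstrap over units
#' (resampled with replacement, profile and radius recomputed per resample)
#' provides the standard error and a central 90% confidence interval.
#'
#' @param profile a `spatial_profile`.
#' @param n_resamples bootstrap resamples, default 2000; 0 skips the
#'   bootstrap.
#' @param ci_level CI level, default 0.90.
#' @param seed integer RNG seed for the bootstrap.
#' @return List with `radius_mm` and (when bootstrapped) `boot`, a
#'   `bootstrap_result`.
#' @export
half_max_radius <- function(profile, n_resamples = 2000, ci_level = 0.90,
                            seed = NULL) {
  stopifnot(inherits(profile, "spatial_profile"))
  point <- half_max_radius_point(profile$distance_mm, profile$relative_rate)
  tab <- attr(profile, "unit_rates")
  breaks <- attr(profile, "breaks_mm")
  boot <- NULL
  if (n_resamples > 0 && !is.null(tab)) {
    boot <- bootstrap_stat(tab, function(sub) {
      p <- bin_profile(sub, breaks)
      half_max_radius_point(p$distance_mm, p$relative_rate)
    }, n_resamples = n_resamples, ci_level = ci_level, seed = seed)
  }
  list(radius_mm = point, boot = boot)
}
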