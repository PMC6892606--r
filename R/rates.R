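# Relative spike rates (unit and population conventions) and rebound index.

# default stimulus-rate window: photostimulus minus the terminal intensity
# ramp (the ramp-down epoch is excluded from "during stimulus" rates unless
# include_ramp = TRUE)
default_stim_window <- function(dataset, include_ramp = FALSE) {
  cond <- dataset$conditions[[1L]]
  dur <- stim_duration(dataset)
  ramp <- if (include_ramp) 0 else (cond$ramp_ms %||% 0) / 1000
  c(0, dur - ramp)
}

#' Per-unit relative spike rate
#'
#' Each unit's spike rate during the photostimulus divided by its baseline
#' rate (500 ms window before onset by convention). Ratios can exceed 1
#' (activated fast-spiking units). Units with zero baseline rate get `NA` and
#' are reported via the `n_zero_baseline` attribute; they are excluded from
#' unit-level ratios but still contribute to the population convention of
#' [relative_rate_population()].
#'
#' @param dataset a `spike_dataset`.
#' @param units unit selection (ids or class label); `NULL` = all.
#' @param stim_window stimulus window (s); default `[0, duration - ramp]`.
#' @param base_window baseline window (s), default `c(-0.5, 0)`.
#' @param include_ramp include the terminal intensity ramp in the stimulus
#'   window.
#' @return Named numeric vector of ratios (names = unit ids).
#' @export
relative_rate_unit <- function(dataset, units = NULL, stim_window = NULL,
                               base_window = c(-0.5, 0),
                               include_ramp = FALSE) {
  stopifnot(inherits(dataset, "spike_dataset"))
  ids <- select_units(dataset, units)
  if (length(ids) == 0L) stop("empty unit selection", call. = FALSE)
  ds <- filter_units(dataset, ids)
  if (is.null(stim_window)) stim_window <- default_stim_window(ds, include_ramp)
  base <- unit_window_rates(ds, base_window)
  stim <- unit_window_rates(ds, stim_window)
  out <- ifelse(base > 0, stim / base, NA_real_)
  names(out) <- ids
  attr(out, "n_zero_baseline") <- sum(base == 0)
  out
}

#' Population relative spike rate
#'
#' Spike rates during photostimulation are first averaged across the
#' population without normalization, then divided by the averaged baseline
#' rate: `mean(stim rates) / mean(baseline rates)`. This reports the total
#' fraction of spiking output under photostimulation and is not the mean of
#' unit-level ratios (high-rate units carry more weight).
#'
#' @inheritParams relative_rate_unit
#' @return Scalar ratio.
#' @export
relative_rate_population <- function(dataset, units = NULL,
                                     stim_window = NULL,
                                     base_window = c(-0.5, 0),
                                     include_ramp = FALSE) {
  stopifnot(inherits(dataset, "spike_dataset"))
  ids <- select_units(dataset, units)
  if (length(ids) == 0L) stop("empty unit selection", call. = FALSE)
  ds <- filter_units(dataset, ids)
  if (is.null(stim_window)) stim_window <- default_stim_window(ds, include_ramp)
  base <- unit_window_rates(ds, base_window)
  stim <- unit_window_rates(ds, stim_window)
  if (mean(base) <= 0)
    stop("mean baseline rate is zero; population relative rate undefined",
         call. = FALSE)
  mean(stim) / mean(base)
}

#' Rebound index after photostimulus offset
#'
#' For each unit: spike rate in a 500 ms window after photostimulus offset,
#' minus the baseline rate (500 ms before onset), normalized by the baseline
#' rate. Positive values are rebound excitation; negative values persisting
#' suppression. The population form averages the per-unit indices across
#' units (zero-baseline units excluded and counted).
#'
#' @param dataset a `spike_dataset`.
#' @param units unit selection; `NULL` = all.
#' @param post_window_s length of the post-offset window (s), default 0.5.
#' @param base_window baseline window (s), default `c(-0.5, 0)`.
#' @param per_unit return the per-unit vector instead of the population mean.
#' @return Population mean rebound index (fraction of baseline), or the
#'   per-unit vector when `per_unit = TRUE`.
#' @export
rebound_index <- function(dataset, units = NULL, post_window_s = 0.5,
                          base_window = c(-0.5, 0), per_unit = FALSE) {
  stopifnot(inherits(dataset, "spike_dataset"))
  check_scalar(post_window_s, "post_window_s", lower = 0, strict_lower = TRUE)
  ids <- select_units(dataset, units)
  if (length(ids) == 0L) stop("empty unit selection", call. = FALSE)
  ds <- filter_units(dataset, ids)
  off <- stim_duration(ds)
  base <- unit_window_rates(ds, base_window)
  post <- unit_window_rates(ds, c(off, off + post_window_s))
  idx <- ifelse(base > 0, (post - base) / base, NA_real_)
  names(idx) <- ids
  if (per_unit) {
    attr(idx, "n_zero_baseline") <- sum(base == 0)
    return(idx)
  }
  n_zero <- sum(base == 0)
  if (n_zero > 0)
    message(n_zero, " unit(s) with zero baseline excluded from rebound index")
  mean(idx, na.rm = TRUE)
}
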