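# In-memory spike dataset: units, spikes, trials, photostimulus conditions.

#' Construct and validate a spike dataset
#'
#' The container used by every electrophysiology stage. Spike times are in
#' seconds relative to photostimulus onset (t = 0); trials span
#' `metadata$trial_window_s`. Referential integrity (spikes -> units, spikes
#' -> trials, trials -> conditions) is enforced at construction, with
#' offending row numbers reported.
#'
#' @param units data frame: `unit_id`, `lateral_distance_um`, `depth_um`, and
#'   optionally `width_ms`, `class_label`, generator ground truth columns.
#' @param spikes data frame: `unit_id`, `trial_id`, `spike_time_s`.
#' @param trials data frame: `trial_id`, `condition_id`.
#' @param conditions named list of [photostim_protocol()] objects (or plain
#'   lists of their fields), keyed by `condition_id`.
#' @param waveforms optional matrix of mean waveforms, one row per unit.
#' @param sampling_rate_hz waveform sampling rate (Hz).
#' @param metadata list; conventionally carries `seed`, `trial_window_s`, the
#'   generator config.
#' @return A `spike_dataset`.
#' @export
spike_dataset <- function(units, spikes, trials, conditions,
                          waveforms = NULL, sampling_rate_hz = 19531.25,
                          metadata = list()) {
  need_cols <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table is missing columns: %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need_cols(units, c("unit_id", "lateral_distance_um"), "units")
  need_cols(spikes, c("unit_id", "trial_id", "spike_time_s"), "spikes")
  need_cols(trials, c("trial_id", "condition_id"), "trials")
  if (anyDuplicated(units$unit_id))
    stop("duplicate unit_id in units table", call. = FALSE)
  if (anyDuplicated(trials$trial_id))
    stop("duplicate trial_id in trials table", call. = FALSE)

  bad <- which(!(spikes$unit_id %in% units$unit_id))
  if (length(bad))
    stop(sprintf("spikes reference unknown unit_id at rows: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  bad <- which(!(spikes$trial_id %in% trials$trial_id))
  if (length(bad))
    stop(sprintf("spikes reference unknown trial_id at rows: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  bad <- which(!(trials$condition_id %in% names(conditions)))
  if (length(bad))
    stop(sprintf("trials reference unknown condition_id at rows: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  tw <- metadata$trial_window_s
  if (!is.null(tw) && nrow(spikes) > 0 &&
      (min(spikes$spike_time_s) < tw[1] - 1e-9 ||
       max(spikes$spike_time_s) > tw[2] + 1e-9))
    stop("spike times fall outside the trial window", call. = FALSE)
  if (!is.null(waveforms) && nrow(waveforms) != nrow(units))
    stop("waveforms must have one row per unit", call. = FALSE)

  structure(list(units = units, spikes = spikes, trials = trials,
                 conditions = conditions, waveforms = waveforms,
                 sampling_rate_hz = sampling_rate_hz, metadata = metadata),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf("Spike dataset: %d units, %d trials, %d spikes, %d condition(s)\n",
              nrow(x$units), nrow(x$trials), nrow(x$spikes),
              length(x$conditions)))
  if (!is.null(x$units$class_label))
    print(table(x$units$class_label))
  invisible(x)
}

#' @export
summary.spike_dataset <- function(object, ...) {
  u <- object$units
  cat(sprintf("Units: %d (distances %g-%g mm)\n", nrow(u),
              min(u$lateral_distance_um) / 1000,
              max(u$lateral_distance_um) / 1000))
  spk <- table(factor(object$spikes$unit_id, levels = u$unit_id))
  cat(sprintf("Spikes per unit: median %g (range %d-%d)\n",
              stats::median(spk), min(spk), max(spk)))
  invisible(object)
}

# subset a dataset's units (keeps all trials/conditions)
filter_units <- function(dataset, keep_ids) {
  dataset$units <- dataset$units[dataset$units$unit_id %in% keep_ids, ,
                                 drop = FALSE]
  dataset$spikes <- dataset$spikes[dataset$spikes$unit_id %in% keep_ids, ,
                                   drop = FALSE]
  if (!is.null(dataset$waveforms))
    dataset$waveforms <- dataset$waveforms[
      match(dataset$units$unit_id, keep_ids), , drop = FALSE]
  dataset
}

# default stimulus duration of a dataset (first condition)
stim_duration <- function(dataset) {
  cond <- dataset$conditions[[1L]]
  dur <- cond$duration_s
  if (is.null(dur)) stop("condition lacks duration_s", call. = FALSE)
  dur
}

# per-unit spike rate (Hz) in a time window, pooled over all trials
unit_window_rates <- function(dataset, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  n_trials <- nrow(dataset$trials)
  s <- dataset$spikes
  inw <- s$spike_time_s >= window[1] & s$spike_time_s < window[2]
  counts <- tapply(as.numeric(inw),
                   factor(s$unit_id, levels = dataset$units$unit_id),
                   sum, default = 0)
  as.numeric(counts) / (n_trials * (window[2] - window[1]))
}
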