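# Spike-waveform width and cell-type classification.
#
# Units with trough-to-peak width < 0.35 ms are putative fast-spiking (FS)
# interneurons; width > 0.45 ms putative pyramidal neurons; the closed band
# [0.35, 0.45] ms is excluded as UNCLASSIFIED (strict inequalities on both
# sides).

#' Trough-to-peak width of a mean spike waveform
#'
#' Width is the interval from the global minimum (trough) to the subsequent
#' maximum (after-peak) of the mean waveform, in ms. Optional 10x cubic-spline
#' upsampling refines sub-sample timing.
#'
#' @param mean_waveform numeric vector, one sample per element.
#' @param sampling_rate_hz sampling rate of the waveform (Hz).
#' @param upsample if `TRUE`, refine trough and peak times on a 10x
#'   cubic-spline interpolation of the waveform.
#' @return Width in ms (positive scalar).
#' @examples
#' w <- -exp(-(1:64 - 20)^2 / 8) + 0.5 * exp(-(1:64 - 30)^2 / 18)
#' trough_to_peak(w, 19531.25)
#' @export
trough_to_peak <- function(mean_waveform, sampling_rate_hz = 19531.25,
                           upsample = FALSE) {
  w <- as.numeric(mean_waveform)
  if (length(w) < 3L || any(!is.finite(w)))
    stop("waveform must be a finite numeric vector (>= 3 samples)",
         call. = FALSE)
  check_scalar(sampling_rate_hz, "sampling_rate_hz", lower = 0,
               strict_lower = TRUE)
  i_trough <- which.min(w)
  i_peak <- which.max(w)
  if (i_trough == 1L || i_trough == length(w))
    stop("not a spike-like waveform: no trough followed by a recovery peak",
         call. = FALSE)
  if (i_peak < i_trough)
    stop("not a spike-like waveform: peak precedes trough", call. = FALSE)
  if (w[i_peak] <= w[i_trough])
    stop("not a spike-like waveform: flat signal", call. = FALSE)
  if (upsample) {
    t10 <- seq(1, length(w), by = 0.1)
    s <- stats::spline(seq_along(w), w, xout = t10, method = "natural")
    i_t <- which.min(s$y)
    i_p <- i_t + which.max(s$y[i_t:length(s$y)]) - 1L
    width_samples <- s$x[i_p] - s$x[i_t]
  } else {
    width_samples <- i_peak - i_trough
  }
  width_samples / sampling_rate_hz * 1000
}

#' Classify a unit by spike width
#'
#' @param width_ms trough-to-peak width in ms (vectorized, all > 0).
#' @return Character vector of labels: `"FS"` (width < 0.35 ms), `"PYR"`
#'   (width > 0.45 ms) or `"UNCLASSIFIED"` (the closed band in between).
#' @examples
#' classify_unit(c(0.3, 0.4, 0.5))
#' @export
classify_unit <- function(width_ms) {
  if (!is.numeric(width_ms) || any(!is.finite(width_ms)) || any(width_ms <= 0))
    stop("`width_ms` must be positive and finite", call. = FALSE)
  ifelse(width_ms < 0.35, "FS",
         ifelse(width_ms > 0.45, "PYR", "UNCLASSIFIED"))
}

#' Classify every unit in a spike dataset
#'
#' Computes trough-to-peak widths from the stored mean waveforms (when
#' present) and appends `width_ms` and `class_label` columns to the units
#' table. Units whose waveform is missing keep any existing width.
#'
#' @param dataset a `spike_dataset`.
#' @param upsample passed to [trough_to_peak()].
#' @return The dataset with `width_ms` and `class_label` filled in.
#' @export
classify_units <- function(dataset, upsample = FALSE) {
  stopifnot(inherits(dataset, "spike_dataset"))
  u <- dataset$units
  if (!is.null(dataset$waveforms)) {
    widths <- vapply(seq_len(nrow(u)), function(i) {
      wf <- dataset$waveforms[i, ]
      if (all(is.na(wf))) return(u$width_ms[i] %||% NA_real_)
      trough_to_peak(wf, dataset$sampling_rate_hz, upsample = upsample)
    }, numeric(1))
    u$width_ms <- widths
  } else if (is.null(u$width_ms)) {
    stop("dataset has neither waveforms nor a width_ms column", call. = FALSE)
  }
  u$class_label <- classify_unit(u$width_ms)
  dataset$units <- u
  dataset
}

`%||%` <- function(a, b) if (is.null(a)) b else a
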