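# Paradoxical-effect scan: population relative rates per cell class across
# light intensities, and detection of the ISN signature (fast-spiking rates
# falling together with pyramidal rates over an initial intensity range).

#' Scan relative spike rates across light intensities
#'
#' Computes the population relative spike rate of fast-spiking and pyramidal
#' units at each light intensity and flags the "paradoxical regime": the
#' maximal initial intensity range over which the FS relative rate is
#' non-increasing while the pyramidal relative rate decreases. The intensity
#' of the FS minimum is reported; in an inhibition-stabilized network it sits
#' near the intensity at which pyramidal activity is essentially silenced,
#' after which FS rates rise again (photocurrent dominating a decoupled
#' network).
#'
#' @param x either a list of `spike_dataset`s (one per intensity, each with
#'   both classes labelled) or a data frame with columns `intensity`,
#'   `fs_rate`, `pyr_rate` of precomputed population relative rates.
#' @param intensities light intensities (mW/mm^2) matching the list `x`.
#' @param tol tolerance on the non-increasing/decreasing comparisons.
#' @param ... rate-window arguments passed to [relative_rate_population()].
#' @return A `paradoxical_scan`: data frame (`intensity`, `fs_rate`,
#'   `pyr_rate`), with attributes `paradoxical_regime` (intensity range or
#'   `NULL`), `fs_minimum_intensity`, `dropped_levels`.
#' @export
paradoxical_scan <- function(x, intensities = NULL, tol = 0, ...) {
  if (is.data.frame(x)) {
    tab <- x
    if (!all(c("intensity", "fs_rate", "pyr_rate") %in% names(tab)))
      stop("data frame needs columns intensity, fs_rate, pyr_rate",
           call. = FALSE)
    dropped <- character(0)
  } else {
    stopifnot(is.list(x), !is.null(intensities),
              length(x) == length(intensities))
    fs <- pyr <- rep(NA_real_, length(x))
    for (k in seq_along(x)) {
      ds <- x[[k]]
      stopifnot(inherits(ds, "spike_dataset"))
      lab <- ds$units$class_label %||% ds$units$class_true
      if (is.null(lab)) stop("datasets must carry class labels", call. = FALSE)
      if (any(lab == "FS")) fs[k] <- relative_rate_population(ds, "FS", ...)
      if (any(lab == "PYR")) pyr[k] <- relative_rate_population(ds, "PYR", ...)
    }
    tab <- data.frame(intensity = intensities, fs_rate = fs, pyr_rate = pyr)
    dropped <- as.character(intensities[!is.finite(fs) | !is.finite(pyr)])
    if (length(dropped))
      message("dropped intensity level(s) missing a class: ",
              paste(dropped, collapse = ", "))
    tab <- tab[is.finite(tab$fs_rate) & is.finite(tab$pyr_rate), ]
  }
  tab <- tab[order(tab$intensity), ]
  if (nrow(tab) < 3L)
    stop("need >= 3 intensity levels with both classes present",
         call. = FALSE)
  fs <- tab$fs_rate; pyr <- tab$pyr_rate
  k <- 1L
  while (k < nrow(tab) &&
         fs[k + 1L] <= fs[k] + tol &&
         pyr[k + 1L] < pyr[k] - tol) k <- k + 1L
  regime <- if (k > 1L) c(tab$intensity[1L], tab$intensity[k]) else NULL
  structure(tab, class = c("paradoxical_scan", "data.frame"),
            paradoxical_regime = regime,
            fs_minimum_intensity = tab$intensity[which.min(fs)],
            dropped_levels = dropped)
}

#' @export
print.paradoxical_scan <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  reg <- attr(x, "paradoxical_regime")
  if (is.null(reg)) {
    cat("No paradoxical regime detected.\n")
  } else {
    cat(sprintf(
      "Paradoxical regime: intensity %g to %g; FS minimum at %g\n",
      reg[1L], reg[2L], attr(x, "fs_minimum_intensity")))
  }
  invisible(x)
}
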