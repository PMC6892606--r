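#' Photostimulus protocol
#'
#' Describes one photostimulation condition: wavelength, time-averaged power,
#' beam geometry and temporal profile. The standard stimulus in this kind of
#' experiment is a near-sinusoidal 40 Hz waveform with a linear intensity ramp
#' over the final 100-200 ms; reported powers are time-averaged.
#'
#' @param wavelength_nm laser wavelength (nm).
#' @param avg_power_mw time-averaged power at the brain surface (mW).
#' @param beam_diameter_4sigma_um Gaussian beam diameter measured at four
#'   standard deviations of the intensity profile (um). Default 400 um.
#' @param temporal_profile `"sinusoid_40hz"` or `"constant"`.
#' @param duration_s photostimulus duration (s).
#' @param ramp_ms duration of the terminal linear intensity ramp (ms).
#' @param center lateral (x, y) position of the beam center (um).
#' @return An object of class `photostim_protocol` (a named list).
#' @examples
#' photostim_protocol(473, avg_power_mw = 1.5)
#' @export
photostim_protocol <- function(wavelength_nm = 473,
                               avg_power_mw = 1.5,
                               beam_diameter_4sigma_um = 400,
                               temporal_profile = c("sinusoid_40hz", "constant"),
                               duration_s = 1.3,
                               ramp_ms = 100,
                               center = c(0, 0)) {
  temporal_profile <- match.arg(temporal_profile)
  check_scalar(wavelength_nm, "wavelength_nm", lower = 0, strict_lower = TRUE)
  check_scalar(avg_power_mw, "avg_power_mw", lower = 0)
  check_scalar(beam_diameter_4sigma_um, "beam_diameter_4sigma_um",
               lower = 0, strict_lower = TRUE)
  check_scalar(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_scalar(ramp_ms, "ramp_ms", lower = 0, upper = duration_s * 1000)
  stopifnot(is.numeric(center), length(center) == 2L)
  structure(list(
    wavelength_nm = wavelength_nm,
    avg_power_mw = avg_power_mw,
    beam_diameter_4sigma_um = beam_diameter_4sigma_um,
    temporal_profile = temporal_profile,
    duration_s = duration_s,
    ramp_ms = ramp_ms,
    center = as.numeric(center)
  ), class = "photostim_protocol")
}

#' @export
print.photostim_protocol <- function(x, ...) {
  cat(sprintf(
    "Photostimulus: %g nm, %g mW (time-averaged), %s, %.2f s, beam 4-sigma %g um\n",
    x$wavelength_nm, x$avg_power_mw, x$temporal_profile, x$duration_s,
    x$beam_diameter_4sigma_um))
  invisible(x)
}

#' Convert laser power to the reported light intensity
#'
#' Reported intensities divide laser power by the beam area using the
#' convention power / (2 * pi * r^2). A disc of radius r has area pi * r^2;
#' the published convention is nonetheless 2 * pi * r^2, so that is the
#' default, with `convention = "disc"` available for sensitivity checks
#' (exactly twice the default).
#'
#' @param power_mw laser power (mW); may be a vector.
#' @param beam_radius_mm beam radius (mm), default 1.
#' @param convention `"published"` (2 pi r^2) or `"disc"` (pi r^2).
#' @return Light intensity in mW/mm^2.
#' @examples
#' intensity_from_power(2 * pi, 1) # 1 mW/mm^2
#' @export
intensity_from_power <- function(power_mw, beam_radius_mm = 1,
                                 convention = c("published", "disc")) {
  convention <- match.arg(convention)
  if (!is.numeric(power_mw) || any(!is.finite(power_mw)))
    stop("`power_mw` must be finite numeric", call. = FALSE)
  check_scalar(beam_radius_mm, "beam_radius_mm", lower = 0, strict_lower = TRUE)
  area <- switch(convention,
                 published = 2 * pi * beam_radius_mm^2,
                 disc = pi * beam_radius_mm^2)
  power_mw / area
}
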