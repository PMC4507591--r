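#' Instrument model for a THz time-domain spectrometer
#'
#' Describes the sampling grid, emitted pulse and noise behaviour of a
#' simulated transmission THz-TDS instrument. The emitted pulse is a
#' single-cycle Gaussian derivative, the typical far-field shape radiated by
#' a photoconductive antenna driven by a ~100 fs laser pulse.
#'
#' Two noise channels are modelled. Multiplicative spectral noise
#' (\code{amplitude_noise_sd}, relative, per frequency bin) emulates
#' shot-to-shot amplitude jitter. Additive white noise in the time domain
#' (\code{additive_noise_sd}, absolute field units) produces a flat spectral
#' noise floor, so the signal-to-noise ratio degrades where the pulse
#' spectrum rolls off at high frequency -- the reason measured spectra are
#' truncated at the top of the usable band. When \code{additive_noise_sd} is
#' \code{NULL} it is derived so that the flat noise floor crosses the clean
#' reference spectrum at \code{dynamic_range_rolloff_freq}.
#'
#' @param time_step sampling interval of the delay line, picoseconds.
#' @param n_points number of samples per trace (>= 64; powers of two keep
#'   the FFT grid convenient).
#' @param pulse_center arrival time of the pulse, ps.
#' @param pulse_width Gaussian width parameter of the pulse, ps. The power
#'   spectrum of the Gaussian-derivative pulse peaks at
#'   \eqn{1/(2\pi\tau)} THz.
#' @param amplitude_noise_sd relative SD of multiplicative per-bin spectral
#'   noise; 0 disables it.
#' @param additive_noise_sd SD of additive time-domain noise in field units;
#'   0 disables it, \code{NULL} derives it from
#'   \code{dynamic_range_rolloff_freq}.
#' @param dynamic_range_rolloff_freq frequency (THz) above which the noise
#'   floor dominates the signal; used only to derive a default
#'   \code{additive_noise_sd}.
#'
#' @return An object of class \code{"thz_instrument"}.
#' @examples
#' inst <- thz_instrument()
#' ref <- make_reference_pulse(inst, seed = 1)
#' @export
thz_instrument <- function(time_step = 0.05, n_points = 1024L,
                           pulse_center = 10, pulse_width = 0.3,
                           amplitude_noise_sd = 0.01,
                           additive_noise_sd = NULL,
                           dynamic_range_rolloff_freq = 1.5) {
  if (!is.numeric(time_step) || time_step <= 0)
    stop_thz("`time_step` must be a positive number of picoseconds")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 64L)
    stop_thz("`n_points` must be an integer >= 64")
  if (pulse_width <= 0) stop_thz("`pulse_width` must be positive")
  if (pulse_center <= 0 || pulse_center >= time_step * n_points)
    stop_thz("`pulse_center` must lie inside the trace window")
  if (amplitude_noise_sd < 0)
    stop_thz("`amplitude_noise_sd` must be >= 0")
  if (!is.null(additive_noise_sd) && additive_noise_sd < 0)
    stop_thz("`additive_noise_sd` must be >= 0")
  if (dynamic_range_rolloff_freq <= 0)
    stop_thz("`dynamic_range_rolloff_freq` must be positive")
  obj <- structure(list(
    time_step = time_step, n_points = n_points,
    pulse_center = pulse_center, pulse_width = pulse_width,
    amplitude_noise_sd = amplitude_noise_sd,
    additive_noise_sd = additive_noise_sd,
    dynamic_range_rolloff_freq = dynamic_range_rolloff_freq
  ), class = "thz_instrument")
  if (is.null(additive_noise_sd))
    obj$additive_noise_sd <- derive_noise_floor(obj)
  obj
}

# Additive-noise SD tied to the dynamic-range rolloff: white time-domain
# noise of SD sigma has a flat spectral floor of sigma*sqrt(N) in the
# (unnormalised) DFT. The SD is set so that a nominally absorbing pellet
# (alpha*d/2 ~ 2.5, i.e. ~50 cm^-1 through 1 mm) still has in-sample
# SNR ~ 20 at the rolloff frequency; because the pulse spectrum falls
# steeply beyond its peak, that SNR collapses to ~1 within another
# half-octave, which is what makes the band above the rolloff unusable.
derive_noise_floor <- function(instrument) {
  ref <- analytic_pulse(instrument)
  spec <- to_frequency(ref)
  mag <- stats::approx(spec$frequencies, Mod(spec$complex_amplitudes),
                       xout = instrument$dynamic_range_rolloff_freq,
                       rule = 2)$y
  nominal_attenuation <- exp(-2.5)
  snr_at_rolloff <- 20
  mag * nominal_attenuation / (snr_at_rolloff * sqrt(instrument$n_points))
}

#' @export
print.thz_instrument <- function(x, ...) {
  cat("THz-TDS instrument model\n")
  cat(sprintf("  window: %d points x %.4g ps (%.4g ps span)\n",
              x$n_points, x$time_step, x$n_points * x$time_step))
  cat(sprintf("  pulse: Gaussian derivative, centre %.3g ps, width %.3g ps\n",
              x$pulse_center, x$pulse_width))
  cat(sprintf("  noise: multiplicative %.3g (rel), additive %.3g (field units)\n",
              x$amplitude_noise_sd, x$additive_noise_sd))
  cat(sprintf("  dynamic-range rolloff: %.3g THz\n",
              x$dynamic_range_rolloff_freq))
  invisible(x)
}

#' Optical profile of one sample class
#'
#' Parameterises the frequency dependence of the absorption coefficient and
#' refractive index of a class of pressed-pellet samples. Ground grain
#' pellets show featureless absorption that rises roughly linearly with
#' frequency in the sub-2 THz window, so the model is
#' \deqn{\alpha(f) = \alpha_0 + s (f - f_{ref}) + A\, b(f)}
#' where \eqn{b(f)} is a raised-cosine bump confined to \code{signal_band}.
#' With the default \code{alpha_ref_freq} at the midpoint of the usable band,
#' \code{alpha_offset} equals the band-averaged absorption level of the
#' class, which is how mean absorption is usually reported.
#'
#' @param class_id integer class code (1..K).
#' @param alpha_offset mean absorption level over the usable band, cm^-1.
#' @param alpha_slope featureless rise of absorption, cm^-1 per THz.
#' @param n_baseline baseline refractive index (> 1; ~1.5 is typical for a
#'   pressed organic pellet).
#' @param signal_band c(f_lo, f_hi) in THz; the class-discriminative
#'   absorption bump is confined to this band.
#' @param signal_amplitude peak height of the discriminative bump, cm^-1
#'   (may be negative; resulting negative absorption is clipped to zero
#'   with a warning when properties are realised).
#' @param alpha_ref_freq frequency (THz) at which \code{alpha_offset} is
#'   anchored; defaults to 0.85, the midpoint of the 0.2--1.5 THz band.
#'
#' @return An object of class \code{"class_profile"}.
#' @seealso [wheat_class_profiles()] for the default eight-class set.
#' @export
class_profile <- function(class_id, alpha_offset, alpha_slope = 20,
                          n_baseline = 1.5,
                          signal_band = c(0.768, 0.850),
                          signal_amplitude = 0,
                          alpha_ref_freq = 0.85) {
  class_id <- as.integer(class_id)
  if (is.na(class_id) || class_id < 1L)
    stop_thz("`class_id` must be a positive integer")
  if (alpha_offset <= 0) stop_thz("`alpha_offset` must be positive (cm^-1)")
  if (n_baseline <= 1) stop_thz("`n_baseline` must exceed 1")
  if (length(signal_band) != 2L || signal_band[1L] >= signal_band[2L])
    stop_thz("`signal_band` must be c(f_lo, f_hi) with f_lo < f_hi")
  structure(list(
    class_id = class_id, alpha_offset = alpha_offset,
    alpha_slope = alpha_slope, n_baseline = n_baseline,
    signal_band = as.numeric(signal_band),
    signal_amplitude = signal_amplitude,
    alpha_ref_freq = alpha_ref_freq
  ), class = "class_profile")
}

#' Default eight-class wheat-variety profiles
#'
#' Eight class profiles emulating pressed pellets of eight wheat varieties.
#' The class-mean absorption levels are the reported band-averaged
#' values 37.1492, 39.4354, 35.3358, 42.1133, 37.5468, 42.2520, 39.8226 and
#' 39.9409 cm^-1 for varieties 1..8. On top of the shared featureless rise,
#' each class carries a weak absorption bump inside \code{signal_band} whose
#' height grows linearly with the class code, so the spectra are linearly
#' decodable into the 1..8 class axis -- the structure the numeric-response
#' PLS model assumes. The refractive index carries a much weaker class trend,
#' so refractive-index models discriminate, but worse than absorption.
#'
#' @param separation multiplier on every class-discriminative component
#'   (offset differences, bump amplitudes, refractive-index trend). 1 gives
#'   the default calibrated separation; 0 makes all classes identical.
#' @param signal_step increment of the bump amplitude per class code, cm^-1.
#' @param signal_band frequency band (THz) holding the discriminative bump.
#' @param equal_offsets if \code{TRUE} all classes share the grand-mean
#'   absorption level, so the bump is the only class information (useful for
#'   planted-band interval-selection studies).
#'
#' @return List of eight \code{class_profile} objects.
#' @examples
#' profs <- wheat_class_profiles()
#' sapply(profs, function(p) p$alpha_offset)
#' @export
wheat_class_profiles <- function(separation = 1, signal_step = 1.5,
                                 signal_band = c(0.768, 0.850),
                                 equal_offsets = FALSE) {
  means <- c(37.1492, 39.4354, 35.3358, 42.1133,
             37.5468, 42.2520, 39.8226, 39.9409)
  grand <- mean(means)
  lapply(1:8, function(i) {
    off <- if (equal_offsets) grand else grand + separation * (means[i] - grand)
    class_profile(
      class_id = i,
      alpha_offset = off,
      alpha_slope = 20,
      n_baseline = 1.5 + separation * 0.003 * (i - 4.5),
      signal_band = signal_band,
      signal_amplitude = separation * signal_step * (i - 4.5)
    )
  })
}

#' Pellet geometry
#'
#' Thickness enters the optical-constant equations; diameter is carried as
#' metadata only. The default 1 mm x 13 mm pellet is the usual geometry for
#' pressed powder samples in transmission THz-TDS.
#'
#' @param thickness pellet thickness (default in mm).
#' @param diameter pellet diameter, same units (metadata).
#' @param units units of both lengths: "mm", "um" or "m".
#' @return An object of class \code{"sample_geometry"} with thickness stored
#'   in mm.
#' @export
sample_geometry <- function(thickness = 1, diameter = 13, units = c("mm", "um", "m")) {
  units <- match.arg(units)
  scale <- switch(units, mm = 1, um = 1e-3, m = 1e3)
  thickness <- thickness * scale
  diameter <- diameter * scale
  if (!is.numeric(thickness) || thickness <= 0)
    stop_thz("`thickness` must be positive")
  structure(list(thickness_mm = thickness, diameter_mm = diameter),
            class = "sample_geometry")
}
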