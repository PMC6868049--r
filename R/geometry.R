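#' Acquisition geometry of an RF frame
#'
#' Describes the sampling grid of a scan-line (pre scan-conversion) RF frame:
#' axial sampling rate, transmit pulse, and frame dimensions. The axial step
#' is derived from the pulse-echo round trip at an assumed speed of sound,
#' `axial_step = c / (2 fs)`.
#'
#' Defaults are plausible for an abdominal curved array working around 3 MHz:
#' 20 MHz sampling, 128 scan lines of 2048 samples (about 7.9 cm depth).
#' A rectangular scan-line grid is used throughout; sector geometry only
#' affects display, not scan-line-domain processing.
#'
#' @param sampling_frequency axial sampling rate in Hz.
#' @param center_frequency pulse center frequency in Hz. Must satisfy
#'   `sampling_frequency >= 4 * center_frequency` (Nyquist with margin).
#' @param n_scanlines number of scan lines (lateral size).
#' @param samples_per_line axial samples per scan line.
#' @param pulse_bandwidth fractional bandwidth: FWHM of the pulse amplitude
#'   spectrum divided by the center frequency.
#' @param sound_speed assumed speed of sound in m/s.
#' @return An object of class `acq_geometry`.
#' @export
acquisition_geometry <- function(sampling_frequency = 20e6,
                                 center_frequency = 3e6,
                                 n_scanlines = 128L,
                                 samples_per_line = 2048L,
                                 pulse_bandwidth = 0.6,
                                 sound_speed = 1540) {
  stopifnot(sampling_frequency > 0, center_frequency > 0,
            pulse_bandwidth > 0, pulse_bandwidth < 2, sound_speed > 0)
  if (sampling_frequency < 4 * center_frequency)
    stop("sampling_frequency must be at least 4x center_frequency")
  n_scanlines <- as.integer(n_scanlines)
  samples_per_line <- as.integer(samples_per_line)
  if (n_scanlines < 1L || samples_per_line < 1L)
    stop("frame dimensions must be >= 1")
  structure(list(
    sampling_frequency = sampling_frequency,
    center_frequency = center_frequency,
    n_scanlines = n_scanlines,
    samples_per_line = samples_per_line,
    pulse_bandwidth = pulse_bandwidth,
    sound_speed = sound_speed,
    axial_step_mm = sound_speed / (2 * sampling_frequency) * 1e3
  ), class = "acq_geometry")
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat(sprintf(
    "<acq_geometry> fs=%.3g MHz fc=%.3g MHz %d lines x %d samples (%.1f mm depth, bw=%.2f)\n",
    x$sampling_frequency / 1e6, x$center_frequency / 1e6,
    x$n_scanlines, x$samples_per_line,
    x$samples_per_line * x$axial_step_mm, x$pulse_bandwidth))
  invisible(x)
}

#' Tissue class parameters for RF simulation
#'
#' Acoustic properties of a homogeneous tissue class: attenuation coefficient,
#' Nakagami envelope statistics, scatterer density and local spectral
#' heterogeneity. These drive the synthetic cohort generator.
#'
#' @param attenuation_db_per_cm_mhz attenuation coefficient in
#'   dB cm^-1 MHz^-1 (`>= 0`), applied at the pulse center frequency.
#' @param nakagami_m Nakagami shape parameter of the envelope (`> 0`).
#' @param nakagami_omega Nakagami scale (mean envelope power, `> 0`).
#' @param scatterer_density scatterers per axial resolution cell. At the
#'   default (dense) setting the speckle reflectivity is effectively
#'   Gaussian per sample; low values give a sparse Bernoulli train.
#' @param spectral_jitter_sd fractional standard deviation of the local
#'   perturbation of the pulse center frequency (drives spectral
#'   heterogeneity between depth blocks and lines).
#' @return An object of class `tissue_params`.
#' @export
tissue_class_params <- function(attenuation_db_per_cm_mhz,
                                nakagami_m,
                                nakagami_omega = 1,
                                scatterer_density = 12,
                                spectral_jitter_sd = 0) {
  if (!is.finite(attenuation_db_per_cm_mhz) || attenuation_db_per_cm_mhz < 0)
    stop("attenuation must be >= 0")
  .check_naka(nakagami_m, nakagami_omega)
  if (!is.finite(scatterer_density) || scatterer_density <= 0)
    stop("scatterer_density must be > 0")
  if (!is.finite(spectral_jitter_sd) || spectral_jitter_sd < 0)
    stop("spectral_jitter_sd must be >= 0")
  structure(list(
    attenuation_db_per_cm_mhz = attenuation_db_per_cm_mhz,
    nakagami_m = nakagami_m,
    nakagami_omega = nakagami_omega,
    scatterer_density = scatterer_density,
    spectral_jitter_sd = spectral_jitter_sd
  ), class = "tissue_params")
}

#' Default tissue classes for the two lesion groups
#'
#' The cohort emulates two lesion classes that differ in attenuation
#' severity (the positive, microvascular-invasion class attenuates more
#' strongly), envelope statistics, and local spectral heterogeneity, so
#' that all three parametric maps carry class signal.
#'
#' @return A list with elements `pos` and `neg`, each a [tissue_class_params()].
#' @export
mvi_class_defaults <- function() {
  list(
    pos = tissue_class_params(attenuation_db_per_cm_mhz = 0.8,
                              nakagami_m = 1.0, nakagami_omega = 1,
                              scatterer_density = 12, spectral_jitter_sd = 0.07),
    neg = tissue_class_params(attenuation_db_per_cm_mhz = 0.5,
                              nakagami_m = 1.0, nakagami_omega = 1,
                              scatterer_density = 12, spectral_jitter_sd = 0.04)
  )
}

# Gaussian-modulated analytic pulse on the frame's sampling grid.
# Fractional bandwidth is the FWHM of the amplitude spectrum / fc.
.gauss_pulse <- function(geometry, fc = geometry$center_frequency) {
  sigma_f <- geometry$pulse_bandwidth * geometry$center_frequency /
    (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  tt <- seq(-3 * sigma_t, 3 * sigma_t, by = 1 / geometry$sampling_frequency)
  env <- exp(-tt^2 / (2 * sigma_t^2))
  list(tt = tt, env = env, p = env * exp(2i * pi * fc * tt),
       sigma_f = sigma_f, sigma_t = sigma_t)
}

#' Pulse analysis band
#'
#' Frequency band over which the pulse amplitude spectrum stays within
#' `drop_db` of its peak; used to restrict window spectra in the spectral
#' heterogeneity map.
#'
#' @param geometry an [acquisition_geometry()].
#' @param drop_db band edge level below the spectral peak, in dB.
#' @return Numeric vector `c(lo, hi)` in Hz.
#' @export
pulse_band <- function(geometry, drop_db = 20) {
  p <- .gauss_pulse(geometry)
  half <- p$sigma_f * sqrt(2 * drop_db * log(10) / 20)
  c(max(0, geometry$center_frequency - half), geometry$center_frequency + half)
}
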