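#' Define a DNA tension probe species
#'
#' A tension probe is a surface-anchored DNA hairpin carrying a FRET pair.
#' Below its force threshold the hairpin is closed and the donor is quenched
#' (dim, short-lifetime); at or above the threshold it opens (bright,
#' long-lifetime). Fluorescence decays in each state are modelled as
#' multi-exponential mixtures; amplitudes are photon-count fractions of the
#' untruncated decay.
#'
#' @param name Character label, e.g. `"hp19"`.
#' @param f_half Force (pN) at which 50% of probes are open at equilibrium.
#' @param t_tol Rupture tolerance (pN) for irreversible tension-gauge-tether
#'   probes, or `NA` for reversible hairpins.
#' @param brightness_open Relative photon emission rate of the open state
#'   (dimensionless, reference 1).
#' @param brightness_closed Relative photon emission rate of the closed
#'   (quenched) state. The implied quenching efficiency is
#'   `1 - brightness_closed / brightness_open`.
#' @param decay_open,decay_closed Two-column matrices (or 2-vectors for a
#'   mono-exponential) with columns `amplitude` (photon fractions summing to 1)
#'   and `lifetime` (ns).
#'
#' @return An object of class `probe_species`.
#' @examples
#' p <- probe_species()
#' p$f_half
#' 1 - p$brightness_closed / p$brightness_open  # quenching efficiency
#' @export
probe_species <- function(name = "hp19",
                          f_half = 19,
                          t_tol = NA_real_,
                          brightness_open = 1.0,
                          brightness_closed = 0.22,
                          decay_open = cbind(amplitude = c(0.85, 0.15),
                                             lifetime = c(2.9, 1.2)),
                          decay_closed = cbind(amplitude = c(0.6, 0.4),
                                               lifetime = c(0.45, 1.3))) {
  decay_open <- as_decay(decay_open)
  decay_closed <- as_decay(decay_closed)
  stopifnot(brightness_open > 0, brightness_closed > 0,
            brightness_closed <= brightness_open)
  if (abs(sum(decay_open[, "amplitude"]) - 1) > 1e-9 ||
      abs(sum(decay_closed[, "amplitude"]) - 1) > 1e-9)
    stop("decay amplitudes must sum to 1")
  if (any(decay_open[, "lifetime"] <= 0) || any(decay_closed[, "lifetime"] <= 0))
    stop("decay lifetimes must be positive")
  structure(list(name = name, f_half = f_half, t_tol = t_tol,
                 brightness_open = brightness_open,
                 brightness_closed = brightness_closed,
                 decay_open = decay_open, decay_closed = decay_closed),
            class = "probe_species")
}

as_decay <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2,
                                   dimnames = list(NULL, c("amplitude", "lifetime")))
  colnames(x) <- c("amplitude", "lifetime")
  x
}

#' @export
print.probe_species <- function(x, ...) {
  cat("Tension probe species:", x$name, "\n")
  cat("  F1/2:", x$f_half, "pN",
      if (!is.na(x$t_tol)) paste0(" (TGT, T_tol ", x$t_tol, " pN)"), "\n")
  cat(sprintf("  brightness open/closed: %.3g / %.3g (QE %.1f%%)\n",
              x$brightness_open, x$brightness_closed,
              100 * (1 - x$brightness_closed / x$brightness_open)))
  invisible(x)
}

#' Describe a TCSPC acquisition
#'
#' Bundles the imaging-physics constants shared by the simulator and the
#' analysis: pixel size, photon-arrival histogram binning, pulse period,
#' exposure scaling, dark counts, illumination profile and the diffraction
#' blur applied to expected photon rates.
#'
#' Defaults mirror a 20 MHz pulsed laser-scanning acquisition recording
#' 400 histogram bins over a 0--12.5 ns window.
#'
#' @param pixel_size Pixel edge (um).
#' @param n_time_bins Number of arrival-time histogram bins.
#' @param time_window Histogram span (ns).
#' @param pulse_period Laser inter-pulse interval (ns); must be at least
#'   `time_window`.
#' @param exposure_scale Expected photons per pixel for a fully open probe
#'   field of unit density at unit illumination.
#' @param dark_counts Expected dark/background counts per pixel (the D term of
#'   the density equation).
#' @param illumination_profile Per-pixel relative excitation map (matrix), or
#'   `NULL` for a flat profile.
#' @param psf_sigma Gaussian point-spread sigma (um) applied to expected rates.
#'
#' @return An object of class `acq_context`.
#' @export
acquisition_context <- function(pixel_size = 0.1,
                                n_time_bins = 400,
                                time_window = 12.5,
                                pulse_period = 50,
                                exposure_scale = 500,
                                dark_counts = 0,
                                illumination_profile = NULL,
                                psf_sigma = 0.1) {
  stopifnot(pixel_size > 0, n_time_bins >= 2, time_window > 0,
            time_window <= pulse_period, exposure_scale > 0,
            dark_counts >= 0, psf_sigma >= 0)
  if (!is.null(illumination_profile) && any(illumination_profile <= 0))
    stop("illumination_profile must be strictly positive")
  structure(list(pixel_size = pixel_size, n_time_bins = n_time_bins,
                 time_window = time_window, pulse_period = pulse_period,
                 exposure_scale = exposure_scale, dark_counts = dark_counts,
                 illumination_profile = illumination_profile,
                 psf_sigma = psf_sigma),
            class = "acq_context")
}

# Bin centers of the arrival-time histogram (ns).
bin_centers <- function(acq) {
  dt <- acq$time_window / acq$n_time_bins
  (seq_len(acq$n_time_bins) - 0.5) * dt
}
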