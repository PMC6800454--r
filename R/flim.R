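#' Fast-FLIM barycenter lifetime map
#'
#' Computes the fit-free average lifetime per pixel as the barycenter (first
#' moment) of the photon arrival-time histogram, with the time origin taken
#' at the global histogram peak — a proxy for the excitation pulse arrival
#' when no instrument response is recorded:
#'
#'   `tau[p] = sum_i(t_i * n_i[p]) / sum_i(n_i[p]) - t_peak`
#'
#' where `t_i` are bin centres and `t_peak` is the centre of the bin with the
#' largest pooled count. Pixels with zero photons are flagged invalid.
#'
#' @param tcspc A `tcspc_image` (from [render_tcspc()] or [read_stack()]).
#' @return An object of class `fastflim_map`: list with `photon_counts`,
#'   `avg_lifetime` (ns; `NA` where no photons), `valid_mask`, `t_peak`, `acq`.
#' @export
fast_flim <- function(tcspc) {
  stopifnot(inherits(tcspc, "tcspc_image"))
  h <- tcspc$histogram
  if (all(h == 0)) stop("empty cube: no photons in any pixel")
  d <- dim(h)
  tc <- bin_centers(tcspc$acq)
  pooled <- apply(h, 3, sum)
  t_peak <- tc[which.max(pooled)]
  flat <- matrix(h, d[1] * d[2], d[3])
  counts <- rowSums(flat)
  bary <- as.vector(flat %*% tc) / counts - t_peak
  bary[counts == 0] <- NA_real_
  structure(list(photon_counts = matrix(counts, d[1], d[2]),
                 avg_lifetime = matrix(bary, d[1], d[2]),
                 valid_mask = matrix(counts > 0, d[1], d[2]),
                 t_peak = t_peak, acq = tcspc$acq),
            class = "fastflim_map")
}

#' @export
print.fastflim_map <- function(x, ...) {
  cat(sprintf("fast-FLIM map %dx%d px; median counts %.0f; median lifetime %.3f ns\n",
              nrow(x$photon_counts), ncol(x$photon_counts),
              stats::median(x$photon_counts),
              stats::median(x$avg_lifetime, na.rm = TRUE)))
  invisible(x)
}

#' Pixel validity mask for lifetime maps
#'
#' A pixel is kept when it has at least `min_photons` photons and its average
#' lifetime does not exceed `max_lifetime`; the defaults (25 photons,
#' 2.97 ns) exclude dim pixels whose barycenter is photon-starved and pixels
#' whose lifetime exceeds the open-probe regime. Boundaries are inclusive:
#' exactly 25 photons or exactly 2.97 ns is valid.
#'
#' @param map A `fastflim_map`.
#' @param min_photons Minimum photon count (inclusive).
#' @param max_lifetime Maximum average lifetime in ns (inclusive).
#' @return Logical matrix.
#' @export
validity_mask <- function(map, min_photons = 25, max_lifetime = 2.97) {
  stopifnot(inherits(map, "fastflim_map"), min_photons > 0, max_lifetime > 0)
  ok <- map$photon_counts >= min_photons &
        !is.na(map$avg_lifetime) & map$avg_lifetime <= max_lifetime
  ok & map$valid_mask
}

#' Quenching efficiency from background-subtracted intensities
#'
#' `QE = (I_open - I_closed) / I_open` on background-subtracted open- and
#' closed-probe reference intensities. Returned as a fraction (0.78 means
#' 78% quenched). A closed intensity above the open intensity yields a
#' negative value with a warning.
#'
#' @param i_open_bs,i_closed_bs Background-subtracted mean intensities of
#'   fully open and fully closed reference surfaces.
#' @return Quenching efficiency (fraction).
#' @export
quenching_efficiency <- function(i_open_bs, i_closed_bs) {
  stopifnot(i_open_bs > 0)
  qe <- (i_open_bs - i_closed_bs) / i_open_bs
  if (qe < 0) warning("closed intensity exceeds open intensity; negative QE")
  qe
}

# Barycenter of a multi-exponential decay truncated at the window T:
# each mono-exponential contributes mean tau - T*exp(-T/tau)/(1-exp(-T/tau)),
# weighted by its within-window photon fraction.
decay_barycenter <- function(decay, time_window) {
  a <- decay[, "amplitude"]; tau <- decay[, "lifetime"]
  w <- a * (1 - exp(-time_window / tau))
  m <- tau - time_window * exp(-time_window / tau) / (1 - exp(-time_window / tau))
  sum(w * m) / sum(w)
}

#' Expected barycenter lifetime of an open/closed probe mixture
#'
#' The photon-weighted average lifetime of a field in which a fraction `f` of
#' probes is open: brighter states contribute more photons, so
#'
#'   `tau(f) = (f * B_o * tau_o + (1 - f) * B_c * tau_c) /
#'             (f * B_o + (1 - f) * B_c)`
#'
#' with `tau_o`, `tau_c` the state barycenters under the same window
#' truncation the histogram applies. This is the noise-free forward model the
#' empirical calibration curve approximates.
#'
#' @param probe A [probe_species()].
#' @param f Fraction of open probes in `[0, 1]` (vectorized).
#' @param time_window Histogram window (ns).
#' @return Expected barycenter lifetime(s), ns.
#' @examples
#' forward_mixture_lifetime(probe_species(), c(0, 0.5, 1))
#' @export
forward_mixture_lifetime <- function(probe, f, time_window = 12.5) {
  stopifnot(all(f >= 0 & f <= 1))
  tau_o <- decay_barycenter(probe$decay_open, time_window)
  tau_c <- decay_barycenter(probe$decay_closed, time_window)
  # within-window detection fractions weight the effective brightness
  det_o <- sum(probe$decay_open[, "amplitude"] *
               (1 - exp(-time_window / probe$decay_open[, "lifetime"])))
  det_c <- sum(probe$decay_closed[, "amplitude"] *
               (1 - exp(-time_window / probe$decay_closed[, "lifetime"])))
  b_o <- probe$brightness_open * det_o
  b_c <- probe$brightness_closed * det_c
  (f * b_o * tau_o + (1 - f) * b_c * tau_c) / (f * b_o + (1 - f) * b_c)
}

# Expected relative intensity (photons detected in-window) of a mixture,
# normalized so the fully open field is 1.
forward_mixture_intensity <- function(probe, f, time_window = 12.5) {
  det_o <- sum(probe$decay_open[, "amplitude"] *
               (1 - exp(-time_window / probe$decay_open[, "lifetime"])))
  det_c <- sum(probe$decay_closed[, "amplitude"] *
               (1 - exp(-time_window / probe$decay_closed[, "lifetime"])))
  b_o <- probe$brightness_open * det_o
  b_c <- probe$brightness_closed * det_c
  (f * b_o + (1 - f) * b_c) / b_o
}

#' Photon-budget precision of the barycenter lifetime
#'
#' Standard error of the barycenter of `N` exponential arrival times with
#' mean `tau`: `tau / sqrt(N)`. For truncated multi-exponential decays the
#' true spread per photon is smaller than `tau`, so this is a conservative
#' (upper-bound) heuristic used to judge whether a photon budget supports a
#' required lifetime contrast.
#'
#' @param n Photon count (vectorized).
#' @param tau Average lifetime (ns).
#' @return Expected standard deviation of the barycenter (ns).
#' @export
lifetime_precision <- function(n, tau) {
  stopifnot(all(n >= 1), tau > 0)
  tau / sqrt(n)
}
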