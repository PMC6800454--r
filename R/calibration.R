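#' Fit an empirical lifetime-vs-percent-open calibration curve
#'
#' Because the probes' multi-exponential decays make the barycenter lifetime
#' a nonlinear function of the open fraction, percent-open maps are obtained
#' by inverting an empirical calibration measured on reference surfaces
#' presenting known open:closed probe ratios. The lifetime curve is fit by
#' least squares to a saturating double-exponential in the open fraction,
#'
#'   `tau(f) = c0 + a1 * (1 - exp(-f / s1)) + a2 * (1 - exp(-f / s2))`
#'
#' and the intensity curve to an affine function of `f`; the quenching
#' efficiency follows from the intensity endpoints. The two rate constants
#' are profiled on a log grid with the amplitudes solved linearly, then
#' polished with Levenberg-Marquardt.
#'
#' @param samples Data frame with columns `fraction` (in `[0, 1]`, must
#'   include 0 and 1), `lifetime` (ns), and optionally `intensity`
#'   (relative).
#' @return Object of class `flim_calibration`: fitted coefficients, a dense
#'   inversion grid, intensity fit with its R-squared, lifetime fit
#'   R-squared, and `quenching_efficiency`.
#' @seealso [percent_open_map()], [predict.flim_calibration()]
#' @examples
#' f <- seq(0, 1, by = 0.1)
#' p <- probe_species()
#' cal <- build_calibration(data.frame(
#'   fraction = f,
#'   lifetime = forward_mixture_lifetime(p, f),
#'   intensity = f * 1 + (1 - f) * p$brightness_closed))
#' cal
#' @export
build_calibration <- function(samples) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("fraction", "lifetime") %in% names(samples)))
  samples <- samples[order(samples$fraction), ]
  f <- samples$fraction; tau <- samples$lifetime
  if (length(unique(f)) < 4 || min(f) > 0 || max(f) < 1)
    stop("need >= 4 distinct fractions including the endpoints 0 and 1")
  if (any(diff(tau) <= 0))
    stop("calibration rejected: sample lifetimes are not strictly ",
         "increasing in open fraction (check surface preparation order)")

  basis <- function(s) 1 - exp(-f / s)
  grid <- exp(seq(log(0.005), log(2), length.out = 40))
  best <- NULL
  for (s1 in grid) for (s2 in grid) {
    if (s2 <= s1) next
    X <- cbind(1, basis(s1), basis(s2))
    co <- tryCatch(qr.solve(X, tau), error = function(e) NULL)
    if (is.null(co)) next
    rss <- sum((tau - X %*% co) ^ 2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, par = c(c0 = co[1], a1 = co[2], a2 = co[3],
                                      s1 = s1, s2 = s2))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      lifetime ~ c0 + a1 * (1 - exp(-fraction / s1)) +
                 a2 * (1 - exp(-fraction / s2)),
      data = samples, start = as.list(best$par),
      lower = c(-Inf, -Inf, -Inf, 1e-4, 1e-4),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  pars <- if (!is.null(fit)) stats::coef(fit) else best$par
  tau_hat <- function(x) {
    pars["c0"] + pars["a1"] * (1 - exp(-x / pars["s1"])) +
      pars["a2"] * (1 - exp(-x / pars["s2"]))
  }
  r2_tau <- 1 - sum((tau - tau_hat(f)) ^ 2) / sum((tau - mean(tau)) ^ 2)

  # dense monotone grid for numerical inversion
  fg <- seq(0, 1, length.out = 2001)
  tg <- tau_hat(fg)
  if (any(diff(tg) <= 0)) stop("fitted calibration curve is not invertible")

  intensity_fit <- NULL; r2_int <- NA_real_; qe <- NA_real_
  if ("intensity" %in% names(samples)) {
    intensity_fit <- stats::lm(intensity ~ fraction, data = samples)
    r2_int <- 1 - sum(stats::residuals(intensity_fit) ^ 2) /
      sum((samples$intensity - mean(samples$intensity)) ^ 2)
    i0 <- stats::predict(intensity_fit, data.frame(fraction = 0))
    i1 <- stats::predict(intensity_fit, data.frame(fraction = 1))
    qe <- quenching_efficiency(i1, i0)
  }

  structure(list(coefficients = pars, samples = samples,
                 grid_fraction = fg, grid_lifetime = tg,
                 r_squared_lifetime = r2_tau,
                 intensity_fit = intensity_fit,
                 r_squared_intensity = r2_int,
                 quenching_efficiency = unname(qe)),
            class = "flim_calibration")
}

#' @export
print.flim_calibration <- function(x, ...) {
  cat("FLIM percent-open calibration\n")
  cat(sprintf("  tau(0) = %.3f ns, tau(1) = %.3f ns (R^2 = %.5f)\n",
              x$grid_lifetime[1], x$grid_lifetime[length(x$grid_lifetime)],
              x$r_squared_lifetime))
  if (!is.na(x$quenching_efficiency))
    cat(sprintf("  quenching efficiency: %.1f%% (intensity R^2 = %.5f)\n",
                100 * x$quenching_efficiency, x$r_squared_intensity))
  invisible(x)
}

#' Predict lifetime from open fraction, or invert
#'
#' @param object A `flim_calibration`.
#' @param fraction Open fractions at which to evaluate the fitted curve.
#' @param lifetime Alternatively, lifetimes (ns) to invert to open fractions
#'   by monotone interpolation of the dense grid; values outside the
#'   calibrated range clamp to 0 or 1.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.flim_calibration <- function(object, fraction = NULL, lifetime = NULL, ...) {
  p <- object$coefficients
  if (!is.null(fraction)) {
    return(p["c0"] + p["a1"] * (1 - exp(-fraction / p["s1"])) +
             p["a2"] * (1 - exp(-fraction / p["s2"])))
  }
  if (!is.null(lifetime)) {
    return(stats::approx(object$grid_lifetime, object$grid_fraction,
                         xout = lifetime, rule = 2)$y)
  }
  stop("supply either `fraction` or `lifetime`")
}

#' @export
plot.flim_calibration <- function(x, ...) {
  plot(x$samples$fraction, x$samples$lifetime,
       xlab = "fraction open", ylab = "barycenter lifetime (ns)",
       main = "Percent-open calibration", ...)
  graphics::lines(x$grid_fraction, x$grid_lifetime)
  invisible(x)
}

#' Per-pixel percent-open map from a lifetime map
#'
#' Inverts the fitted calibration at each valid pixel's barycenter lifetime.
#' Lifetimes below the closed-state endpoint map to 0, above the open-state
#' endpoint to 1; the fraction of such clamped pixels is recorded.
#'
#' @param map A `fastflim_map`.
#' @param cal A `flim_calibration`.
#' @param mask Logical validity mask (default [validity_mask()] with its
#'   standard thresholds).
#' @return Matrix of open fractions in `[0, 1]` (`NA` outside the mask) with
#'   attribute `clamped_fraction`.
#' @export
percent_open_map <- function(map, cal, mask = validity_mask(map)) {
  stopifnot(inherits(map, "fastflim_map"), inherits(cal, "flim_calibration"))
  tau <- map$avg_lifetime
  lo <- cal$grid_lifetime[1]; hi <- cal$grid_lifetime[length(cal$grid_lifetime)]
  out <- matrix(NA_real_, nrow(tau), ncol(tau))
  out[mask] <- predict(cal, lifetime = tau[mask])
  clamped <- mean(tau[mask] < lo | tau[mask] > hi)
  attr(out, "clamped_fraction") <- clamped
  out
}

#' Relative probe density map
#'
#' Converts illumination-corrected photon counts into probe density relative
#' to the cell-free bilayer, accounting for the fact that open probes are
#' brighter than quenched closed probes:
#'
#'   `rho = (I - D) / ((I0 - D) / (1 - QE) * F + (I0 - D) * (1 - F))`
#'
#' where `I` is the per-pixel count, `D` dark counts, `I0` the cell-free
#' bilayer reference count, `QE` the quenching efficiency and `F` the
#' percent-open map. For linear (hairpin-free) probes pass `percent_open = 0`.
#'
#' @param counts Per-pixel photon counts, illumination-profile corrected.
#' @param percent_open Per-pixel open fraction map (or scalar).
#' @param i0 Scalar reference count on cell-free bilayer.
#' @param dark Scalar dark counts.
#' @param qe Quenching efficiency (fraction, strictly between 0 and 1).
#' @return Matrix of relative densities.
#' @examples
#' density_map(counts = matrix(200), percent_open = 0.5, i0 = 100,
#'             dark = 0, qe = 0.78)  # ~0.721
#' @export
density_map <- function(counts, percent_open, i0, dark = 0, qe) {
  stopifnot(qe > 0, qe < 1)
  if (i0 <= dark) stop("degenerate reference: I0 must exceed dark counts")
  f <- percent_open
  (counts - dark) / ((i0 - dark) / (1 - qe) * f + (i0 - dark) * (1 - f))
}
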