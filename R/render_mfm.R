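#' Render an excitation-polarization sweep of a scene
#'
#' Images the scene once per excitation polarization angle. Open (loaded)
#' probes are oriented along the local force axis; their fluorophore dipole
#' is uniformly distributed on the circle perpendicular to that axis, so the
#' ring-averaged excitation probability for in-plane polarization at angle
#' `alpha` is
#'
#'   `I(alpha) proportional to (1 - sin^2(theta) * cos^2(alpha - phi)) / 2`
#'
#' with tilt `theta` from the substrate normal and azimuth `phi`. Closed
#' probes are quenched (mechano-selection) and contribute only an
#' unmodulated residual. Poisson noise is applied per frame.
#'
#' @param scene A [build_scene()] result with orientation defined wherever
#'   `fraction_open_field > 0`.
#' @param probe A [probe_species()].
#' @param acq An [acquisition_context()]; `exposure_scale` is the expected
#'   photons per frame for a fully open, unit-density, vertically-averaged
#'   pixel.
#' @param sweep Excitation polarization angles (degrees); default 73 frames
#'   at 2.5 degree steps spanning 180 degrees.
#' @param closed_residual Fraction of closed-state brightness surviving
#'   static quenching (default 0.02).
#' @param seed Integer seed.
#' @return Object of class `polarization_stack`: `images` (rows x cols x
#'   n_angles array), `angles`, `acq`.
#' @export
render_polarization_stack <- function(scene, probe, acq,
                                      sweep = seq(0, 180, by = 2.5),
                                      closed_residual = 0.02, seed = 1) {
  stopifnot(inherits(scene, "scene"), inherits(acq, "acq_context"),
            length(unique(sweep)) >= 4)
  if (any(scene$fraction_open_field > 0 &
          is.na(scene$orientation_field$tilt)))
    stop("orientation field undefined where fraction_open > 0")
  nr <- scene$shape[1]; nc <- scene$shape[2]
  illum <- acq$illumination_profile
  if (is.null(illum)) illum <- matrix(1, nr, nc)

  open_amp <- scene$density_field * scene$fraction_open_field *
    probe$brightness_open * acq$exposure_scale * illum
  closed_amp <- scene$density_field * (1 - scene$fraction_open_field) *
    probe$brightness_open * closed_residual * acq$exposure_scale * illum

  th <- scene$orientation_field$tilt * pi / 180
  ph <- scene$orientation_field$azimuth * pi / 180
  s2 <- sin(th) ^ 2
  s2[is.na(s2)] <- 0; ph[is.na(ph)] <- 0

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  imgs <- array(0L, dim = c(nr, nc, length(sweep)))
  for (k in seq_along(sweep)) {
    a <- sweep[k] * pi / 180
    # ring-averaged dipole excitation, normalized to 1 at its maximum over
    # angles for an in-plane pixel so exposure_scale keeps its meaning
    mod <- (1 - s2 * cos(a - ph) ^ 2)
    lam <- open_amp * mod + closed_amp + acq$dark_counts
    imgs[, , k] <- stats::rpois(nr * nc, lam)
  }
  structure(list(images = imgs, angles = sweep, acq = acq),
            class = "polarization_stack")
}

# Brute-force oracle: average excitation probability of dipoles uniformly
# distributed on the circle perpendicular to a force axis with tilt theta and
# azimuth phi (degrees), probed with in-plane polarization alpha (degrees).
# Retained as an independent check of the closed-form ring model.
dipole_ring_mc <- function(theta, phi, alpha, n = 1e5, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  th <- theta * pi / 180; ph <- phi * pi / 180
  u <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  # orthonormal basis of the plane perpendicular to u
  e1 <- if (abs(u[3]) < 0.9) c(-u[2], u[1], 0) else c(1, 0, 0) - u[1] * u
  e1 <- e1 / sqrt(sum(e1 ^ 2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  psi <- stats::runif(n, 0, 2 * pi)
  d <- outer(cos(psi), e1) + outer(sin(psi), e2)
  vapply(alpha * pi / 180, function(a) {
    e <- c(cos(a), sin(a), 0)
    mean((d %*% e) ^ 2)
  }, numeric(1))
}
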