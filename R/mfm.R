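#' Fit sinusoidal polarization modulation per pixel
#'
#' Least-squares fit of `I(alpha) = C - A * cos(2 * (alpha - phi))` at every
#' masked pixel, solved in closed form through the constant and second-order
#' Fourier coefficients of the sweep (the design matrix is shared by all
#' pixels). `phi` follows the intensity-minimum convention — the azimuth at
#' which excitation is least efficient, i.e. the in-plane direction of the
#' force axis — and is reported modulo 180 degrees. Pixels with `A = 0` have
#' undefined phase and are flagged.
#'
#' @param stack A `polarization_stack`.
#' @param mask Logical matrix selecting tension (mechano-selected) pixels;
#'   default all.
#' @return Object of class `orientation_map`: matrices `offset`, `amplitude`,
#'   `phase` (degrees in `[0, 180)`), `residual` (root-mean-square), and
#'   `phase_undefined` flags, plus the angles used.
#' @export
fit_modulation <- function(stack, mask = NULL) {
  stopifnot(inherits(stack, "polarization_stack"))
  d <- dim(stack$images)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  ang <- stack$angles * pi / 180
  if (length(unique(stack$angles %% 180)) < 4)
    stop("need at least 4 distinct polarization angles")
  X <- cbind(1, cos(2 * ang), sin(2 * ang))
  Y <- t(matrix(stack$images, d[1] * d[2], d[3]))  # frames x pixels
  beta <- qr.solve(X, Y)                           # 3 x pixels, shared design
  C <- beta[1, ]; a <- beta[2, ]; b <- beta[3, ]
  A <- sqrt(a ^ 2 + b ^ 2)
  # I = C + a cos2a + b sin2a = C - A cos(2(a - phi)) with a = -A cos 2phi
  phase <- (atan2(-b, -a) / 2 * 180 / pi) %% 180
  resid <- sqrt(colMeans((Y - X %*% beta) ^ 2))
  shape_it <- function(v) matrix(ifelse(as.vector(mask), v, NA_real_), d[1], d[2])
  structure(list(offset = shape_it(C), amplitude = shape_it(A),
                 phase = shape_it(phase), residual = shape_it(resid),
                 phase_undefined = shape_it(A) <= .Machine$double.eps ^ 0.5,
                 angles = stack$angles),
            class = "orientation_map")
}

#' Tilt angle from modulation depth
#'
#' For a fluorophore dipole uniformly distributed on the circle
#' perpendicular to the force axis, the modulation ratio of the
#' excitation-polarization response is `m = sin^2(theta) / (2 - sin^2(theta))`,
#' inverted here as `theta = asin(sqrt(2 m / (1 + m)))`. Below `cone_angle`
#' the response is nearly flat, so small tilts are flagged as inside the
#' vertical cone rather than trusted.
#'
#' @param offset,amplitude Matrices (or scalars) `C` and `A` from
#'   [fit_modulation()].
#' @param cone_angle Tilts below this (degrees) set the `vertical_cone` flag.
#' @return List with `theta` (degrees from the substrate normal, in
#'   `[0, 90]`), `vertical_cone` flags, and `saturated` flags where `A > C`
#'   forced clipping to `m = 1`.
#' @examples
#' tilt_angle(offset = 3, amplitude = 1)$theta  # m = 1/3 -> 45 degrees
#' @export
tilt_angle <- function(offset, amplitude, cone_angle = 20) {
  if (any(offset <= 0, na.rm = TRUE)) stop("offset C must be positive")
  m <- amplitude / offset
  saturated <- !is.na(m) & m > 1
  m <- pmin(m, 1)
  theta <- asin(sqrt(2 * m / (1 + m))) * 180 / pi
  list(theta = theta, vertical_cone = !is.na(theta) & theta < cone_angle,
       saturated = saturated)
}

#' Per-podosome and per-cell tilt summaries
#'
#' Averages the tilt map over each podosome's ring pixels (after dropping
#' saturated fits and, optionally, high-residual pixels), then takes the
#' unweighted mean of podosome means as the per-cell tilt. Also reports the
#' fraction of ring pixels inside the vertical cone and an angular histogram.
#'
#' @param records Podosome records from [detect_podosomes()], with
#'   `ring_mask` entries.
#' @param tilt A [tilt_angle()] result evaluated on an [fit_modulation()]
#'   map aligned with the records.
#' @param max_residual Optional residual cutoff; pixels above it are dropped
#'   (requires `residual` attribute-bearing map, pass via `residual`).
#' @param residual Optional residual matrix from [fit_modulation()].
#' @param breaks Histogram breaks in degrees.
#' @return List with `per_podosome` data frame (`id`, `mean_theta`,
#'   `cone_fraction`, `n_pixels`), scalar `cell_mean_theta`,
#'   `cell_cone_fraction`, and `histogram` (counts per angular bin).
#' @export
podosome_tilt_summary <- function(records, tilt, residual = NULL,
                                  max_residual = Inf,
                                  breaks = seq(0, 90, by = 10)) {
  per <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    sel <- rec$ring_mask
    keep <- sel & !tilt$saturated & !is.na(tilt$theta)
    if (!is.null(residual)) keep <- keep & residual <= max_residual
    th <- tilt$theta[keep]
    data.frame(id = rec$id,
               mean_theta = if (length(th)) mean(th) else NA_real_,
               cone_fraction = if (length(th)) mean(tilt$vertical_cone[keep])
                               else NA_real_,
               n_pixels = length(th))
  })
  per <- do.call(rbind, per)
  list(per_podosome = per,
       cell_mean_theta = mean(per$mean_theta, na.rm = TRUE),
       cell_cone_fraction = mean(per$cone_fraction, na.rm = TRUE),
       histogram = graphics::hist(per$mean_theta, breaks = breaks,
                                  plot = FALSE)$counts)
}

#' Emission anisotropy with G-factor correction
#'
#' `r = (I_par - G * I_perp) / (I_par + 2 * G * I_perp)`, where the G-factor
#' calibrates the polarization bias of the detection path from an isotropic
#' reference (`G = mean(ref_par) / mean(ref_perp)`). Pixels with a
#' non-positive denominator are masked to `NA`.
#'
#' @param i_par,i_perp Parallel and perpendicular emission images.
#' @param g G-factor from [g_factor()].
#' @return Anisotropy map (same shape as inputs).
#' @export
anisotropy <- function(i_par, i_perp, g = 1) {
  stopifnot(g > 0)
  den <- i_par + 2 * g * i_perp
  r <- (i_par - g * i_perp) / den
  r[den <= 0] <- NA_real_
  r
}

#' @rdname anisotropy
#' @param reference_par,reference_perp Emission images of an isotropic
#'   reference fluorophore in solution.
#' @export
g_factor <- function(reference_par, reference_perp) {
  stopifnot(all(reference_par > 0), all(reference_perp > 0))
  mean(reference_par) / mean(reference_perp)
}
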