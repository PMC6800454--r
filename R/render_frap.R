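#' Render a FRAP bleach-recovery movie
#'
#' Simulates photobleaching of a disk in a uniform fluid bilayer followed by
#' lateral diffusion. The concentration field evolves by exact 2-D diffusion:
#' between consecutive frames separated by `dt` the field is convolved with
#' a Gaussian kernel of variance `2 * D * dt` (the heat-equation propagator,
#' applied with periodic boundaries so total probe mass is conserved).
#' Optionally Poisson photon noise is applied on readout; the underlying
#' concentration field is also returned noise-free.
#'
#' @param d_coef Diffusion coefficient (um^2/s).
#' @param bleach_radius Radius `w` of the bleached disk (um); the disk must
#'   fit in the field with a margin of at least `3 * w`.
#' @param acq An [acquisition_context()] providing `pixel_size` and
#'   `exposure_scale` (expected photons per pixel per frame at unit
#'   concentration).
#' @param frames Frame times (s), strictly increasing; frames at or before
#'   `t_bleach` are pre-bleach.
#' @param shape Field size in pixels.
#' @param t_bleach Bleach time (s).
#' @param residual Concentration left in the disk immediately after bleach.
#' @param noise Apply Poisson noise to the returned movie?
#' @param seed Integer seed (used only when `noise = TRUE`).
#' @return Object of class `frap_movie`: `movie` (rows x cols x n_frames),
#'   `concentration` (noise-free), `times`, `roi` (logical disk mask),
#'   `bleach_radius`, `t_bleach`, `pixel_size`.
#' @export
render_frap_movie <- function(d_coef, bleach_radius, acq, frames,
                              shape = NULL, t_bleach = 0, residual = 0.1,
                              noise = TRUE, seed = 1) {
  stopifnot(d_coef >= 0, bleach_radius > 0, all(diff(frames) > 0))
  px <- acq$pixel_size
  if (is.null(shape)) {
    n <- ceiling(8 * bleach_radius / px)
    shape <- c(n, n)
  }
  if (min(shape) * px < 8 * bleach_radius)
    stop("field must fit the bleach disk with margin >= 3w")
  nr <- shape[1]; nc <- shape[2]
  ctr <- c(nr, nc) / 2 * px
  d2 <- outer(((seq_len(nr) - 0.5) * px - ctr[1]) ^ 2,
              ((seq_len(nc) - 0.5) * px - ctr[2]) ^ 2, `+`)
  roi <- d2 <= bleach_radius ^ 2

  conc <- matrix(1, nr, nc)
  movie <- array(0, dim = c(nr, nc, length(frames)))
  concs <- array(0, dim = c(nr, nc, length(frames)))
  bleached <- FALSE
  prev_t <- frames[1]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (k in seq_along(frames)) {
    t <- frames[k]
    if (k > 1) conc <- diffuse_field(conc, d_coef, t - prev_t, px)
    if (!bleached && t >= t_bleach) {
      conc[roi] <- residual
      bleached <- TRUE
    }
    concs[, , k] <- conc
    lam <- conc * acq$exposure_scale
    movie[, , k] <- if (noise) stats::rpois(nr * nc, lam) else lam
    prev_t <- t
  }
  structure(list(movie = movie, concentration = concs, times = frames,
                 roi = roi, bleach_radius = bleach_radius,
                 t_bleach = t_bleach, pixel_size = px),
            class = "frap_movie")
}

#' Propagate a concentration field by free 2-D diffusion
#'
#' Convolution with the Gaussian heat kernel of standard deviation
#' `sqrt(2 * D * dt)`, using periodic boundaries (mass-conserving). A kernel
#' below half a pixel is too poorly sampled on the grid to be accurate and
#' raises an error; take a larger `dt` or coarser sampling instead.
#'
#' @param field Concentration matrix.
#' @param d_coef Diffusion coefficient (um^2/s).
#' @param dt Time step (s).
#' @param pixel_size Pixel edge (um).
#' @return Diffused matrix.
#' @export
diffuse_field <- function(field, d_coef, dt, pixel_size) {
  if (d_coef == 0 || dt == 0) return(field)
  sigma_px <- sqrt(2 * d_coef * dt) / pixel_size
  if (sigma_px < 0.5)
    stop("diffusion kernel sigma ", signif(sigma_px, 3),
         " px < 0.5 px: step too small for grid accuracy")
  gaussian_blur(field, sigma_px)
}
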