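# Shared fixtures: small probe/scene builders used across test files.

test_probe <- function(...) probe_species(...)

# a uniform open-fraction field with no podosomes, cell covering everything
uniform_scene <- function(f = 0, shape = c(24, 24), tilt = NA, azimuth = NA,
                          seed = 1) {
  sc <- build_scene(scene_config(shape = shape, n_podosomes = 0,
                                 n_clusters = 0, cell_margin = 0),
                    seed = seed)
  sc$fraction_open_field[] <- f
  if (!is.na(tilt)) sc$orientation_field$tilt[] <- tilt
  if (!is.na(azimuth)) sc$orientation_field$azimuth[] <- azimuth
  sc
}

# analytic calibration samples for a probe on a fraction grid
calibration_samples <- function(probe, fractions = seq(0, 1, by = 0.1)) {
  data.frame(fraction = fractions,
             lifetime = forward_mixture_lifetime(probe, fractions),
             intensity = mtflim:::forward_mixture_intensity(probe, fractions))
}

# noiseless density image with ideal podosomes stamped on a flat background
ideal_podosome_image <- function(centres_px, core_radius_um = 0.3,
                                 core_density = 0.1, shape = c(80, 80),
                                 pixel_size = 0.1, background = 1) {
  img <- matrix(background, shape[1], shape[2])
  for (i in seq_len(nrow(centres_px))) {
    d2 <- outer((seq_len(shape[1]) - centres_px[i, 1]) ^ 2,
                (seq_len(shape[2]) - centres_px[i, 2]) ^ 2, `+`)
    img[d2 <= (core_radius_um / pixel_size) ^ 2] <- core_density
  }
  img
}
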