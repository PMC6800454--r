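test_that("empty scene is a bare bilayer", {
  sc <- build_scene(scene_config(shape = c(32, 32), n_podosomes = 0,
                                 n_clusters = 0), seed = 1)
  expect_true(all(sc$density_field == 1))
  expect_true(all(sc$fraction_open_field == 0))
  expect_null(sc$podosome_truth)
})

test_that("podosome geometry matches the configured ring model", {
  cfg <- scene_config(shape = c(64, 64), n_podosomes = 1,
                      core_radius = 0.3, ring_outer_radius = 1.0,
                      ring_fraction_open = 0.10, core_density = 0.1)
  sc <- build_scene(cfg, seed = 4)
  p <- sc$podosome_truth
  d <- sqrt(outer((seq_len(64) - p$row[1]) ^ 2,
                  (seq_len(64) - p$col[1]) ^ 2, `+`)) * sc$pixel_size
  ring <- d > 0.3 & d <= 1.0 & sc$cell_mask
  core <- d <= 0.3
  expect_true(all(sc$fraction_open_field[ring] == 0.10))
  expect_true(all(sc$density_field[core] <= 0.1))
  expect_true(all(sc$fraction_open_field[!sc$cell_mask] == 0))
})

test_that("scenes are deterministic in (config, seed) and vary with seed", {
  cfg <- scene_config(shape = c(64, 64), n_podosomes = 3)
  a <- build_scene(cfg, seed = 7)
  b <- build_scene(cfg, seed = 7)
  c <- build_scene(cfg, seed = 8)
  expect_identical(a$density_field, b$density_field)
  expect_identical(a$podosome_truth, b$podosome_truth)
  expect_equal(nrow(c$podosome_truth), 3)
  expect_false(identical(a$podosome_truth$row, c$podosome_truth$row))
})

test_that("impossible placement reports the seed", {
  cfg <- scene_config(shape = c(40, 40), n_podosomes = 10,
                      min_separation = 10)
  expect_error(build_scene(cfg, seed = 3), "seed 3")
})

test_that("dark-field render is Poisson around the dark rate with uniform arrivals", {
  sc <- uniform_scene(0, shape = c(50, 50))
  sc$density_field[] <- 0
  acq <- acquisition_context(exposure_scale = 100, dark_counts = 2,
                             psf_sigma = 0, n_time_bins = 50)
  cube <- render_tcspc(sc, test_probe(), acq, seed = 9)
  counts <- apply(cube$histogram, c(1, 2), sum)
  expect_equal(mean(counts), 2, tolerance = 3 * sqrt(2 / 2500) / 2)
  # uniform arrivals: first and second half of the window equally occupied
  pooled <- apply(cube$histogram, 3, sum)
  expect_equal(sum(pooled[1:25]) / sum(pooled), 0.5, tolerance = 0.05)
})

test_that("closed-field expected rate follows the Poisson forward model", {
  sc <- uniform_scene(0, shape = c(100, 100))
  probe <- test_probe()
  acq <- acquisition_context(exposure_scale = 200, psf_sigma = 0)
  cube <- render_tcspc(sc, probe, acq, seed = 2)
  counts <- apply(cube$histogram, c(1, 2), sum)
  det_c <- sum(probe$decay_closed[, "amplitude"] *
               (1 - exp(-12.5 / probe$decay_closed[, "lifetime"])))
  expected <- 200 * probe$brightness_closed * det_c
  se <- sqrt(expected / 1e4)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("renders are bitwise reproducible under a fixed seed", {
  sc <- build_scene(scene_config(shape = c(40, 40), n_podosomes = 1), seed = 5)
  acq <- acquisition_context(exposure_scale = 80)
  a <- render_tcspc(sc, test_probe(), acq, seed = 11)
  b <- render_tcspc(sc, test_probe(), acq, seed = 11)
  expect_identical(a$histogram, b$histogram)
  sa <- render_polarization_stack(sc, test_probe(), acq, seed = 12)
  sb <- render_polarization_stack(sc, test_probe(), acq, seed = 12)
  expect_identical(sa$images, sb$images)
})

test_that("per-pixel counts obey the photon-count (Poisson) law", {
  sc <- uniform_scene(0.5, shape = c(4, 4))
  acq <- acquisition_context(exposure_scale = 60, psf_sigma = 0,
                             n_time_bins = 20)
  reps <- vapply(1:1000, function(s) {
    cube <- render_tcspc(sc, test_probe(), acq, seed = s)
    as.vector(apply(cube$histogram, c(1, 2), sum))
  }, numeric(16))
  vm <- apply(reps, 1, stats::var) / rowMeans(reps)
  expect_true(all(vm > 0.9 & vm < 1.1))
})

test_that("high-budget open-field barycenter matches the mixture forward model", {
  probe <- test_probe()
  sc <- uniform_scene(1, shape = c(40, 40))
  cube <- render_tcspc(sc, probe,
                       acquisition_context(exposure_scale = 5000,
                                           psf_sigma = 0), seed = 3)
  fm <- fast_flim(cube)
  bin_w <- 12.5 / 400
  expect_lt(abs(mean(fm$avg_lifetime) - forward_mixture_lifetime(probe, 1)),
            2 * bin_w)
})
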