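timeline_scene <- function(seed = 3, shape = c(200, 200), n = 4) {
  build_scene(scene_config(shape = shape, n_podosomes = n,
                           min_separation = 2.5), seed = seed)
}

test_that("event validation rejects unknown kinds and out-of-span times", {
  sc <- timeline_scene()
  expect_error(simulate_timeline(sc, 0:5, list(list(time = 1, kind = "zap",
                                                    roi = NULL))),
               "unknown event kind")
  expect_error(simulate_timeline(sc, 0:5, list(list(time = 99,
                                                    kind = "bleach",
                                                    roi = NULL))),
               "outside the timeline span")
})

test_that("without events the fields are stationary and mass is conserved", {
  sc <- timeline_scene()
  tl <- simulate_timeline(sc, seq(0, 30, by = 2), d_coef = 1.4)
  m <- vapply(tl$frames, function(f) sum(f$density), numeric(1))
  expect_lt(diff(range(m)) / m[1], 1e-6)
  expect_identical(tl$frames[[1]]$density, tl$frames[[10]]$density)
})

test_that("photocleavage empties the roi then refills monotonically by diffusion", {
  sc <- timeline_scene()
  roi <- list(center = c(100, 100), radius = 3)
  roim <- mtflim:::resolve_roi(roi, sc$shape, sc$pixel_size)
  times <- seq(-6, 30, by = 1.5)
  tl <- simulate_timeline(sc, times, list(
    list(time = 0, kind = "photocleave", roi = roi, residual = 0)),
    d_coef = 1.4)
  k0 <- which(times == 0)
  expect_true(all(tl$frames[[k0]]$density[roim] == 0))
  roi_mean <- vapply(tl$frames, function(f) mean(f$density[roim]),
                     numeric(1))
  expect_true(all(diff(roi_mean[k0:length(times)]) >= -1e-9))
  expect_gt(roi_mean[length(times)], 0.8)
})

test_that("podosomes inside the cleaved roi retract by the response factor", {
  sc <- timeline_scene()
  roi <- list(center = c(sc$podosome_truth$row[1],
                         sc$podosome_truth$col[1]), radius = 2)
  times <- seq(-6, 12, by = 1.5)
  tl <- simulate_timeline(sc, times, list(
    list(time = 0, kind = "photocleave", roi = roi, residual = 0.05,
         response_factor = 0.75)), d_coef = 1.4)
  k_pre <- 1; k_post <- length(times)
  expect_equal(tl$core_radii[k_post, 1], 0.75 * tl$core_radii[k_pre, 1])
  expect_equal(tl$core_radii[k_post, 2], tl$core_radii[k_pre, 2])
})

test_that("tension-gauge tethers rupture only above their tolerance", {
  sc <- timeline_scene()
  # roi centred on a podosome so it is guaranteed to contain ring pixels
  roi <- list(center = c(sc$podosome_truth$row[1],
                         sc$podosome_truth$col[1]), radius = 2)
  times <- seq(-3, 9, by = 1.5)
  hardy <- probe_species(t_tol = 56) # applied f_half = 19 pN < T_tol
  tl1 <- simulate_timeline(sc, times, list(
    list(time = 0, kind = "tgt_sink", roi = roi, rate = 5, duration = 2)),
    d_coef = 1.4, probe = hardy)
  expect_identical(tl1$frames[[1]]$density,
                   tl1$frames[[length(times)]]$density)
  frail <- probe_species(t_tol = 12) # ruptures under 19 pN load
  tl2 <- simulate_timeline(sc, times, list(
    list(time = 0, kind = "tgt_sink", roi = roi, rate = 5, duration = 2)),
    d_coef = 1.4, probe = frail)
  k0 <- which(times == 0)
  ring_roi <- mtflim:::resolve_roi(roi, sc$shape, sc$pixel_size) &
    sc$fraction_open_field > 0
  expect_true(any(ring_roi))
  expect_lt(mean(tl2$frames[[k0]]$density[ring_roi]),
            mean(tl2$frames[[1]]$density[ring_roi]))
})

test_that("apply_perturbation validates and re-simulates", {
  sc <- timeline_scene()
  tl <- simulate_timeline(sc, seq(-3, 9, by = 1.5), d_coef = 1.4)
  expect_error(apply_perturbation(tl, list(time = 0)), "kind")
  tl2 <- apply_perturbation(tl, list(
    time = 0, kind = "bleach", roi = list(center = c(100, 100), radius = 2),
    residual = 0.1))
  expect_length(tl2$events, 1)
  roim <- mtflim:::resolve_roi(list(center = c(100, 100), radius = 2),
                               sc$shape, sc$pixel_size)
  k0 <- which(tl2$times == 0)
  expect_lt(mean(tl2$frames[[k0]]$density[roim]), 0.2)
})

test_that("cleavage recovery matches a FRAP experiment of the same geometry", {
  sc <- build_scene(scene_config(shape = c(240, 240), n_podosomes = 14,
                                 min_separation = 2.2), seed = 3)
  roi <- list(center = c(120, 120), radius = 3)
  roim <- mtflim:::resolve_roi(roi, sc$shape, sc$pixel_size)
  times <- seq(-9, 30, by = 1.5)
  tl <- simulate_timeline(sc, times, list(
    list(time = 0, kind = "photocleave", roi = roi, residual = 0.05)),
    d_coef = 1.4)
  rec <- recovery_after_cleavage(lapply(tl$frames, `[[`, "tension"),
                                 times, roim, 0)
  mv <- render_frap_movie(1.4, 3,
                          acquisition_context(pixel_size = 0.1,
                                              exposure_scale = 100),
                          frames = times, noise = FALSE, seed = 1,
                          residual = 0.05, shape = c(240, 240))
  sig <- apply(mv$movie, 3, function(m) mean(m[mv$roi]))
  t_frap <- frap_halftime(times, sig, 0)$t_half
  expect_lt(abs(rec$fit$t_half - t_frap) / t_frap, 0.25)
})
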