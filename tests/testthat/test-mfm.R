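noiseless_stack <- function(theta, phi, angles = seq(0, 180, by = 2.5),
                            amp = 1000, shape = c(4, 4)) {
  s2 <- sin(theta * pi / 180) ^ 2
  imgs <- array(0, dim = c(shape, length(angles)))
  for (k in seq_along(angles)) {
    a <- angles[k] * pi / 180
    imgs[, , k] <- amp * (1 - s2 * cos(a - phi * pi / 180) ^ 2)
  }
  structure(list(images = imgs, angles = angles,
                 acq = acquisition_context()), class = "polarization_stack")
}

test_that("the dipole-ring closed form agrees with brute-force Monte-Carlo", {
  angles <- seq(0, 180, by = 15)
  for (theta in c(0, 30, 45, 60, 90)) {
    mc <- mtflim:::dipole_ring_mc(theta, 40, angles, n = 1e5, seed = 5)
    cf <- 0.5 * (1 - sin(theta * pi / 180) ^ 2 *
                   cos((angles - 40) * pi / 180) ^ 2)
    expect_lt(max(abs(mc - cf) / cf), 0.01)
  }
})

test_that("modulation fit recovers phase and amplitude from clean sweeps", {
  st <- noiseless_stack(60, 30)
  om <- fit_modulation(st)
  expect_equal(om$phase[1, 1], 30, tolerance = 0.5)
  m_true <- sin(60 * pi / 180) ^ 2 / (2 - sin(60 * pi / 180) ^ 2)
  expect_equal(om$amplitude[1, 1] / om$offset[1, 1], m_true,
               tolerance = 1e-6)
  # constant sweep: zero amplitude, undefined phase flag
  st0 <- noiseless_stack(0, 0)
  om0 <- fit_modulation(st0)
  expect_lt(om0$amplitude[1, 1], 1e-6)
  expect_true(om0$phase_undefined[1, 1])
  expect_error(fit_modulation(structure(list(
    images = st$images[, , 1:3, drop = FALSE], angles = st$angles[1:3],
    acq = st$acq), class = "polarization_stack")), "4 distinct")
})

test_that("tilt inversion matches the ring-model closed form", {
  expect_equal(tilt_angle(offset = 3, amplitude = 1)$theta, 45)
  expect_equal(tilt_angle(offset = 1, amplitude = 1)$theta, 90)
  t0 <- tilt_angle(offset = 5, amplitude = 0)
  expect_equal(t0$theta, 0)
  expect_true(t0$vertical_cone)
  ts <- tilt_angle(offset = 1, amplitude = 1.2)
  expect_true(ts$saturated)
  expect_equal(ts$theta, 90)
  expect_error(tilt_angle(offset = -1, amplitude = 0), "positive")
})

test_that("forward-inverse tilt recovery is exact without noise, close with noise", {
  probe <- test_probe()
  for (theta in c(25, 30, 45, 60, 75, 90)) {
    st <- noiseless_stack(theta, 70)
    om <- fit_modulation(st)
    th <- tilt_angle(om$offset, om$amplitude)$theta[1, 1]
    expect_lt(abs(th - theta), 1)
  }
  # Poisson noise at >= 5e3 photons per pixel per sweep
  sc <- uniform_scene(1, shape = c(16, 16), tilt = 60, azimuth = 70)
  st <- render_polarization_stack(
    sc, probe, acquisition_context(exposure_scale = 150, psf_sigma = 0),
    closed_residual = 0, seed = 8)
  om <- fit_modulation(st)
  th <- tilt_angle(om$offset, om$amplitude)$theta
  expect_lt(abs(mean(th) - 60), 5)
  expect_lt(abs(mean(om$phase) - 70), 3)
})

test_that("rotating the scene azimuth rotates the fitted phase equally", {
  base <- fit_modulation(noiseless_stack(50, 20))$phase[1, 1]
  for (delta in c(30, 77, 160)) {
    ph <- fit_modulation(noiseless_stack(50, 20 + delta))$phase[1, 1]
    expect_equal((ph - base) %% 180, delta %% 180, tolerance = 1e-6)
  }
})

test_that("near-vertical tilts trip the cone flag at realistic noise", {
  probe <- test_probe()
  hits <- vapply(1:20, function(s) {
    sc <- uniform_scene(1, shape = c(5, 5), tilt = 12, azimuth = 40,
                        seed = s)
    st <- render_polarization_stack(
      sc, probe, acquisition_context(exposure_scale = 150, psf_sigma = 0),
      closed_residual = 0, seed = 100 + s)
    om <- fit_modulation(st)
    mean(tilt_angle(om$offset, om$amplitude)$vertical_cone)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("anisotropy and G-factor follow their definitions", {
  expect_equal(g_factor(matrix(4, 2, 2), matrix(2, 2, 2)), 2)
  expect_equal(anisotropy(2, 1, g = 1), 0.25)
  expect_equal(anisotropy(3, 3, g = 1), 0)
  expect_equal(anisotropy(5, 0, g = 1), 1)
  # isotropic noisy reference averages to zero
  set.seed(3)
  ipar <- matrix(stats::rpois(1e4, 5000), 100)
  iperp <- matrix(stats::rpois(1e4, 2500), 100)
  g <- g_factor(ipar, iperp)
  expect_equal(mean(anisotropy(ipar, iperp, g)), 0, tolerance = 0.005)
  r <- anisotropy(matrix(0), matrix(0), 1)
  expect_true(is.na(r[1, 1]))
})
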