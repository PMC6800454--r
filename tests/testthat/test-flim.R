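make_cube <- function(hist_array, acq = acquisition_context()) {
  structure(list(histogram = hist_array, acq = acq, probe_name = "x"),
            class = "tcspc_image")
}

test_that("barycenter handles point masses and weighted mixtures exactly", {
  acq <- acquisition_context(n_time_bins = 125, time_window = 12.5)
  centers <- (seq_len(125) - 0.5) * 0.1
  h <- array(0L, dim = c(1, 2, 125))
  # pixel 1: all photons in the bin centred at 2.05 ns
  h[1, 1, which.min(abs(centers - 2.05))] <- 100L
  # pixel 2: point masses at 1.05 and 3.05 ns with counts 1:3
  h[1, 2, which.min(abs(centers - 1.05))] <- 25L
  h[1, 2, which.min(abs(centers - 3.05))] <- 75L
  fm <- fast_flim(make_cube(h, acq))
  # peak origin is the modal bin (2.05 here, 3.05 for pooled? pooled peak is 3.05)
  t_peak <- fm$t_peak
  expect_equal(fm$avg_lifetime[1, 1], 2.05 - t_peak, tolerance = 1e-12)
  expect_equal(fm$avg_lifetime[1, 2],
               (1.05 * 25 + 3.05 * 75) / 100 - t_peak, tolerance = 1e-12)
})

test_that("truncated mono-exponential matches its closed form", {
  # barycenter of tau = 1.5 ns truncated at 12.5 ns
  tau <- 1.5; T <- 12.5
  expected <- tau - T * exp(-T / tau) / (1 - exp(-T / tau))
  probe <- probe_species(decay_open = c(1, tau), decay_closed = c(1, 0.5))
  expect_equal(mtflim:::decay_barycenter(probe$decay_open, T), expected,
               tolerance = 1e-12)
  expect_equal(expected, 1.497, tolerance = 1e-3)
})

test_that("all-zero cubes are rejected", {
  h <- array(0L, dim = c(4, 4, 10))
  expect_error(fast_flim(make_cube(h, acquisition_context(n_time_bins = 10))),
               "empty cube")
})

test_that("validity mask thresholds are inclusive at both boundaries", {
  fm <- structure(list(
    photon_counts = matrix(c(24, 25, 1e4, 400), 2),
    avg_lifetime = matrix(c(1.0, 2.97, 3.1, 2.0), 2),
    valid_mask = matrix(TRUE, 2, 2)), class = "fastflim_map")
  m <- validity_mask(fm)
  expect_false(m[1, 1]) # 24 photons: below the count cutoff
  expect_true(m[2, 1])  # exactly 25 photons and exactly 2.97 ns: kept
  expect_false(m[1, 2]) # bright but too long-lived
  expect_true(m[2, 2])
})

test_that("quenching efficiency follows its defining ratio", {
  expect_equal(quenching_efficiency(1000, 220), 0.78)
  expect_equal(quenching_efficiency(123, 123), 0)
  expect_equal(quenching_efficiency(55, 0), 1)
  expect_warning(qe <- quenching_efficiency(100, 150), "negative")
  expect_lt(qe, 0)
})

test_that("mixture lifetime interpolates brightness-weighted endpoints", {
  probe <- test_probe()
  T <- 12.5
  tau_o <- mtflim:::decay_barycenter(probe$decay_open, T)
  tau_c <- mtflim:::decay_barycenter(probe$decay_closed, T)
  expect_equal(forward_mixture_lifetime(probe, 0), tau_c)
  expect_equal(forward_mixture_lifetime(probe, 1), tau_o)
  # hand arithmetic with effectively untruncated single-lifetime states
  p2 <- probe_species(brightness_closed = 0.22,
                      decay_open = c(1, 2.8), decay_closed = c(1, 0.9))
  got <- forward_mixture_lifetime(p2, 0.5, time_window = 1e4)
  expect_equal(got, (0.5 * 1 * 2.8 + 0.5 * 0.22 * 0.9) /
                    (0.5 * 1 + 0.5 * 0.22), tolerance = 1e-6)
  expect_equal(got, 2.457, tolerance = 2e-3)
})

test_that("mixture lifetime matches Monte-Carlo photon sampling", {
  probe <- test_probe()
  set.seed(42)
  f <- 0.35; T <- 12.5; n <- 2e5
  sample_state <- function(decay, n) {
    comp <- sample(seq_len(nrow(decay)), n, replace = TRUE,
                   prob = decay[, "amplitude"])
    stats::rexp(n, rate = 1 / decay[comp, "lifetime"])
  }
  n_open <- round(n * f * probe$brightness_open /
                  (f * probe$brightness_open +
                   (1 - f) * probe$brightness_closed))
  t_all <- c(sample_state(probe$decay_open, n_open),
             sample_state(probe$decay_closed, n - n_open))
  t_all <- t_all[t_all <= T] # gated histogram discards late photons
  expect_equal(mean(t_all), forward_mixture_lifetime(probe, f),
               tolerance = 0.01)
})

test_that("lifetime precision heuristic matches exponential sampling", {
  expect_equal(lifetime_precision(400, 2), 0.1)
  expect_equal(lifetime_precision(1e12, 2), 0, tolerance = 1e-5)
  set.seed(7)
  mc <- stats::sd(replicate(2000, mean(stats::rexp(100, 1 / 2))))
  expect_equal(mc, lifetime_precision(100, 2), tolerance = 0.2 * 0.2)
})

test_that("pixel-to-pixel lifetime scatter scales as N^(-1/2)", {
  probe <- test_probe()
  sc <- uniform_scene(0.3, shape = c(40, 40))
  Ns <- c(25, 100, 400, 1600)
  sds <- vapply(seq_along(Ns), function(i) {
    cube <- render_tcspc(sc, probe,
                         acquisition_context(exposure_scale = Ns[i],
                                             psf_sigma = 0), seed = 30 + i)
    stats::sd(fast_flim(cube)$avg_lifetime)
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(sds) ~ log(Ns)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})
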