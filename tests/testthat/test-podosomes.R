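test_that("noiseless detection recovers every podosome with sub-pixel centroids", {
  ctrs <- rbind(c(20, 20), c(20, 60), c(50, 30), c(60, 60), c(35, 45))
  img <- ideal_podosome_image(ctrs)
  recs <- detect_podosomes(img, background = 1)
  expect_length(recs, 5)
  got <- do.call(rbind, lapply(recs, `[[`, "centroid"))
  d <- apply(ctrs, 1, function(ct)
    min(sqrt(rowSums(sweep(got, 2, ct) ^ 2))))
  expect_true(all(d <= 1))
  for (r in recs) expect_false(any(r$core_mask & r$ring_mask))
})

test_that("uniform background yields no detections", {
  expect_length(detect_podosomes(matrix(1, 40, 40), 1), 0)
  expect_error(detect_podosomes(matrix(1, 4, 4), 0), "background")
})

test_that("touching cores 0.8 um apart are split by the watershed line", {
  img <- ideal_podosome_image(rbind(c(30, 26), c(30, 34)))  # 0.8 um apart
  recs <- detect_podosomes(img, background = 1)
  expect_length(recs, 2)
  cols <- sort(vapply(recs, function(r) r$centroid[2], numeric(1)))
  expect_equal(cols, c(26, 34), tolerance = 1.5)
})

test_that("depletion metrics reproduce direct arithmetic", {
  img <- ideal_podosome_image(rbind(c(40, 40)), core_density = 0.3,
                              core_radius_um = 0.4)
  rec <- detect_podosomes(img, 1)[[1]]
  m <- depletion_metrics(rec, img, background = 1)
  expect_equal(m$depletion_pct, 70, tolerance = 1)
  expect_equal(m$core_radius, 0.4, tolerance = 0.05)
  # zero and full depletion endpoints
  flat <- matrix(1, 80, 80)
  expect_equal(depletion_metrics(rec, flat, 1)$depletion_pct, 0)
  expect_equal(depletion_metrics(rec, flat * 0, 1)$depletion_pct, 100)
  edge <- rec; edge$centroid <- c(1, 1)
  expect_error(depletion_metrics(edge, img, 1), "exits")
})

test_that("measured depletion deepens with true core exclusion", {
  deps <- vapply(c(0.5, 0.3, 0.1, 0.02), function(cd) {
    img <- ideal_podosome_image(rbind(c(40, 40)), core_density = cd)
    rec <- detect_podosomes(img, 1)[[1]]
    depletion_metrics(rec, img, 1)$depletion_pct
  }, numeric(1))
  expect_true(all(diff(deps) > 0))
  expect_true(all(abs(deps - (100 * (1 - c(0.5, 0.3, 0.1, 0.02)))) < 2))
})

test_that("ring statistics follow the stated averaging conventions", {
  img <- ideal_podosome_image(rbind(c(25, 25), c(25, 55)))
  recs <- detect_podosomes(img, 1)
  fmap <- matrix(0, 80, 80)
  fmap[recs[[1]]$ring_mask] <- 0.08
  fmap[recs[[2]]$ring_mask] <- 0.12
  st <- ring_tension_stats(recs, fmap)
  expect_equal(st$per_podosome$mean_F, c(0.08, 0.12))
  expect_equal(st$cell_mean_F, 0.10)
  # podosomes with too few valid pixels are flagged and excluded
  vm <- matrix(FALSE, 80, 80)
  vm[recs[[1]]$ring_mask] <- TRUE
  expect_warning(st2 <- ring_tension_stats(recs, fmap, valid_mask = vm,
                                           min_valid_pixels = 1e5),
                 regexp = "valid ring")
  st3 <- ring_tension_stats(recs, fmap, valid_mask = vm)
  expect_true(st3$per_podosome$excluded[2])
  expect_equal(st3$cell_mean_F, 0.08)
})

test_that("clusters are detected away from depletion zones only", {
  img <- ideal_podosome_image(rbind(c(20, 20), c(60, 60)))
  for (ct in list(c(20, 60), c(60, 20), c(40, 40))) {
    d2 <- outer((1:80 - ct[1]) ^ 2, (1:80 - ct[2]) ^ 2, `+`)
    img[d2 <= 16] <- 2
  }
  recs <- detect_podosomes(img, 1)
  clus <- detect_clusters(img, recs)
  expect_length(clus, 3)
  expect_equal(vapply(clus, `[[`, numeric(1), "mean_density"), rep(2, 3))
  # a bright rim around a podosome is rejected by the exclusion radius
  d2 <- outer((1:80 - 20) ^ 2, (1:80 - 20) ^ 2, `+`)
  img2 <- ideal_podosome_image(rbind(c(20, 20)))
  img2[d2 > 25 & d2 <= 49] <- 2
  expect_length(detect_clusters(img2, detect_podosomes(img2, 1)), 0)
  expect_length(detect_clusters(matrix(1, 40, 40), list()), 0)
})

test_that("per-cell normalization uses the brightest podosome as reference", {
  vals <- c(10, 20, 40, 6, 3)
  bright <- c(5, 9, 2, 1, 8)
  cell <- c("a", "a", "a", "b", "b")
  got <- normalize_by_brightest(vals, bright, cell)
  expect_equal(got, c(10 / 20, 1, 2, 2, 1))
})
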