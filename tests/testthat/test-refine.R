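test_that("refinement region is the (dilated) mask intersection", {
  a <- array(FALSE, c(10, 10, 4)); a[1:4, 1:4, ] <- TRUE
  b <- array(FALSE, c(10, 10, 4)); b[7:10, 7:10, ] <- TRUE
  expect_equal(sum(refinement_region(binary_mask(a), binary_mask(b),
                                     0)$data), 0)
  # subset identity at dilation 0
  s1 <- array(FALSE, c(10, 10, 4)); s1[3:5, 3:5, 2:3] <- TRUE
  s2 <- array(FALSE, c(10, 10, 4)); s2[2:7, 2:7, 1:4] <- TRUE
  expect_identical(refinement_region(binary_mask(s1), binary_mask(s2),
                                     0)$data, s1)
  expect_error(refinement_region(binary_mask(a),
                                 binary_mask(array(FALSE, c(9, 9, 4)))),
               "congruent")
})

test_that("juxta phantom: the collar is small relative to the nodule mask", {
  jx <- make_phantom(phantom_spec("juxta_vascular", size = c(40, 40, 40),
                                  radius_mm = 6, tube_radius_mm = 3,
                                  noise_sd = 5, seed = 2))
  # idealized candidates straight from the construction
  sc1 <- jx$truth$tube
  sc2 <- jx$truth$sphere
  sr <- refinement_region(sc1, sc2, 1)
  expect_gt(sum(sr$data), 0)
  expect_lt(sum(sr$data), 0.5 * sum(sc2$data))
})

test_that("shape index distinguishes caps, ridges, and flat regions", {
  g <- noduleseg:::coord_grids(c(33, 33, 33), c(1, 1, 1))
  r2 <- (g[[1]] - 16)^2 + (g[[2]] - 16)^2 + (g[[3]] - 16)^2
  ball <- image_volume(100 * exp(-r2 / 30))
  si_b <- shape_index(ball, scale = 1.5)
  expect_gte(si_b$si[17, 17, 17], 0.9)

  ph <- make_phantom(phantom_spec("vessel_tube", size = c(32, 32, 32),
                                  tube_radius_mm = 3, noise_sd = 0))
  si_t <- shape_index(ph$volume, scale = 1.5)
  expect_equal(si_t$si[17, 17, 16], 0.75, tolerance = 0.08)

  flat <- shape_index(image_volume(array(5, c(12, 12, 12))), scale = 1)
  expect_equal(unique(as.vector(flat$si)), 0.5)
  expect_false(any(flat$defined))
  expect_true(all(si_b$si >= 0 & si_b$si <= 1))
})

test_that("empty refinement region leaves the nodule mask untouched", {
  sc2 <- binary_mask(array(c(TRUE, FALSE), c(8, 8, 2)))
  sr <- binary_mask(array(FALSE, c(8, 8, 2)))
  vol <- image_volume(array(rnorm(128), c(8, 8, 2)))
  expect_identical(cluster_refine(sr, sc2, vol, seed = 1)$data, sc2$data)
})

test_that("refinement region smaller than k skips with a warning", {
  d <- c(8, 8, 2)
  sc2 <- binary_mask(array(TRUE, d))
  sr <- array(FALSE, d); sr[1, 1, 1] <- TRUE
  vol <- image_volume(array(rnorm(prod(d)), d))
  expect_warning(out <- cluster_refine(binary_mask(sr), sc2, vol,
                                       k_clusters = 2, seed = 1),
                 "skipping")
  expect_identical(out$data, sc2$data)
})

test_that("K-means recovers a separable construction exactly", {
  # two well-separated intensity populations inside S_r
  d <- c(12, 12, 3)
  vol_arr <- array(0, d)
  vol_arr[1:6, , ] <- 0
  vol_arr[7:12, , ] <- 100
  sr <- array(TRUE, d)
  sc2 <- binary_mask(array(TRUE, d))
  refined <- cluster_refine(binary_mask(sr), sc2, image_volume(vol_arr),
                            k_clusters = 2, seed = 3)
  kept <- refined$data
  # exactly one of the two constructed halves is retained
  frac_hi <- mean(kept[7:12, , ])
  frac_lo <- mean(kept[1:6, , ])
  expect_true((frac_hi > 0.99 && frac_lo < 0.01) ||
                (frac_lo > 0.99 && frac_hi < 0.01))
})

test_that("refinement is local and deterministic, and improves the juxta fit", {
  jx <- make_phantom(phantom_spec("juxta_vascular", size = c(40, 40, 40),
                                  radius_mm = 6, tube_radius_mm = 3,
                                  noise_sd = 5, seed = 6))
  seg <- suppressWarnings(
    segment_nodule(jx$volume, init = list(seed = c(28, 20, 20),
                                          radius_mm = 4),
                   params = acm_params(max_iter = 80, roi_margin_mm = 6,
                                       seed = 6)))
  sc2 <- seg$mask
  fld <- structure_tensor(jx$volume, 1, 2)
  sc1 <- fdf_region_grow(jx$volume, fld,
                         vessel_params(intensity_range =
                                         c(100 * exp(-1.125), 150),
                                       seeds = list(c(20, 20, 20))))
  sr <- refinement_region(sc1, sc2, 1)
  r1 <- cluster_refine(sr, sc2, jx$volume, k_clusters = 3, seed = 6)
  r2 <- cluster_refine(sr, sc2, jx$volume, k_clusters = 3, seed = 6)
  expect_identical(r1$data, r2$data)              # determinism
  expect_true(all((r1$data != sc2$data) <= sr$data))  # locality
  expect_lt(jaccard_error(r1, jx$truth$sphere),
            jaccard_error(sc2, jx$truth$sphere))
  # removed voxels lie on the tube side of the junction
  removed <- sc2$data & !r1$data
  expect_gt(mean(jx$truth$tube$data[removed]), 0.6)
})
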