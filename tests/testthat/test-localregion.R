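test_that("radius and neighbour-count bounds follow the 8 mm rule", {
  expect_equal(radius_bound(0.5), 8)
  expect_equal(radius_bound(0.75), 5)   # floor(5.33)
  expect_equal(radius_bound(4.0), 1)    # lower clamp
  expect_equal(k_bound(0.5, 4), 50)     # floor(pi * 64 / 4)
  expect_equal(k_bound(1.0, 4), 12)     # floor(pi * 16 / 4)
  expect_error(radius_bound(0), "positive")
  expect_error(k_bound(1, 0), "positive")
})

test_that("doubling K0 halves the neighbour bound (floor-wise)", {
  for (sp in c(0.5, 0.7, 1)) {
    expect_lte(k_bound(sp, 8), ceiling(k_bound(sp, 4) / 2))
    expect_gte(k_bound(sp, 8), floor(k_bound(sp, 4) / 2) - 1)
  }
})

test_that("constant feature fields accept the full neighbourhood", {
  v <- image_volume(matrix(5, 15, 15))
  ff <- build_feature_field(v)
  sel <- select_local_region(c(8, 8), ff, local_region_spec(r = 4, k = 10))
  expect_true(sel$accepted_full)
  expect_equal(length(sel$idx), length(sel$r_l) + 1)
})

test_that("a sharp feature boundary triggers the KNN fallback", {
  img <- cbind(matrix(0, 15, 8), matrix(100, 15, 7))
  ff <- build_feature_field(image_volume(img))
  sel <- select_local_region(c(8, 8), ff, local_region_spec(r = 4, k = 6))
  expect_false(sel$accepted_full)
  expect_equal(length(sel$idx), 7)  # centre + k nearest
})

test_that("selection equals the exhaustive brute-force rule on random fields", {
  set.seed(99)
  for (rep in 1:30) {
    img <- matrix(sample(c(0, 50, 100), 81, TRUE), 9, 9) +
      matrix(rnorm(81, 0, 5), 9, 9)
    ff <- build_feature_field(image_volume(img), asm_window = 3)
    spec <- local_region_spec(r = sample(2:3, 1), k = sample(3:6, 1))
    v <- c(sample(3:7, 1), sample(3:7, 1))
    got <- select_local_region(v, ff, spec)
    ref <- select_local_region_bruteforce(v, ff, spec)
    expect_equal(got$accepted_full, ref$accepted_full)
    expect_setequal(got$idx, ref$idx)
  }
})

test_that("fallback never happens on constant fields, always on checkerboards", {
  const <- build_feature_field(image_volume(matrix(1, 11, 11) +
                                              0 * matrix(0, 11, 11)))
  chk_img <- matrix(rep(c(0, 100), length.out = 121), 11, 11)
  chk <- build_feature_field(image_volume(chk_img), asm_window = 3)
  spec <- local_region_spec(r = 3, k = 5)
  n_fb_const <- 0; n_fb_chk <- 0
  for (i in 5:7) for (j in 5:7) {
    n_fb_const <- n_fb_const +
      !select_local_region(c(i, j), const, spec)$accepted_full
    n_fb_chk <- n_fb_chk +
      !select_local_region(c(i, j), chk, spec)$accepted_full
  }
  expect_equal(n_fb_const, 0)
  expect_equal(n_fb_chk, 9)
})

test_that("local density means split a region by the contour sign", {
  img <- cbind(matrix(0, 10, 5), matrix(100, 10, 5))
  ff <- build_feature_field(image_volume(img))
  phi <- cbind(matrix(-1, 10, 5), matrix(1, 10, 5))
  region <- seq_len(100)
  lm <- local_density_means(region, phi, ff, sigma = 0.02)
  expect_s3_class(lm$p1, "density_estimate")
  expect_gt(pdf_distance(lm$p1, lm$p2), 0.1)
  # one-sided region: the empty side is NULL-flagged
  lm1 <- local_density_means(which(phi >= 0), phi, ff, sigma = 0.02)
  expect_null(lm1$p2)
  expect_s3_class(lm1$p1, "density_estimate")
  # identical features on both sides: distance 0
  ffc <- build_feature_field(image_volume(matrix(3, 10, 10)))
  lmc <- local_density_means(region, phi, ffc, sigma = 0.02)
  expect_equal(pdf_distance(lmc$p1, lmc$p2), 0, tolerance = 1e-9)
  expect_error(local_density_means(integer(0), phi, ff), "empty")
})

test_that("separation monotonicity: larger value split, larger distance", {
  phi <- cbind(matrix(-1, 10, 5), matrix(1, 10, 5))
  # interior columns only: away from the edge the texture level is
  # uniform, so the split is a pure intensity effect
  interior <- which(col(matrix(0, 10, 10)) %in% c(1:3, 8:10))
  dists <- sapply(c(20, 50, 100), function(contrast) {
    img <- cbind(matrix(0, 10, 5), matrix(contrast, 10, 5))
    # intensity anchor outside the measured region fixes the min-max
    # normalization range so the split scales with the contrast
    img[5, 5] <- 100
    ff <- build_feature_field(image_volume(img, spacing = c(1, 1)),
                              intensity_range = c(0, 100))
    lm <- local_density_means(interior, phi, ff, sigma = 0.02)
    pdf_distance(lm$p1, lm$p2)
  })
  expect_true(all(diff(dists) > 0))
})
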