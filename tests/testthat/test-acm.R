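test_that("smoothed Heaviside/Dirac have the stated analytic structure", {
  for (eps in c(0.5, 1.5, 3)) {
    expect_equal(smoothed_heaviside(0, eps), 0.5)
    t <- seq(-10, 10, by = 0.37)
    expect_equal(smoothed_heaviside(t, eps) + smoothed_heaviside(-t, eps),
                 rep(1, length(t)))
    # numeric derivative of H matches the Dirac within 1e-6
    h <- 1e-5
    num <- (smoothed_heaviside(t + h, eps) -
              smoothed_heaviside(t - h, eps)) / (2 * h)
    expect_equal(num, smoothed_dirac(t, eps), tolerance = 1e-6)
  }
  expect_error(smoothed_heaviside(0, -1), "positive")
})

test_that("fuzzy membership separates two populations and sums to one", {
  img <- cbind(matrix(0, 20, 10), matrix(100, 20, 10)) +
    matrix(rnorm(400, 0, 3), 20, 20)
  ff <- build_feature_field(image_volume(img))
  u <- fuzzy_membership(ff, m = 2, seed = 1)
  expect_true(all(u >= 0 & u <= 1))
  expect_gt(mean(u[, 11:20]), 0.9)   # bright side is the nodule cluster
  expect_lt(mean(u[, 1:10]), 0.1)
  # hard assignment agrees with 2-means on the same features
  km <- kmeans(ff$features[, c("intensity", "asm_level")], 2, nstart = 5)
  bright_cl <- which.max(tapply(ff$features[, "intensity"], km$cluster,
                                mean))
  expect_gt(mean((u > 0.5) == (km$cluster == bright_cl)), 0.98)
  # larger m is fuzzier (memberships pulled towards 1/2)
  u4 <- fuzzy_membership(ff, m = 6, seed = 1)
  expect_lt(mean(abs(u4 - 0.5)), mean(abs(u - 0.5)))
  expect_error(fuzzy_membership(build_feature_field(
    image_volume(matrix(1, 8, 8))), 2, 1), "constant")
})

test_that("gradient stop function is 1 on flat images, small on edges", {
  g <- stop_function(image_volume(matrix(7, 16, 16)))
  expect_equal(g, array(1, c(16, 16)))
  img <- cbind(matrix(0, 16, 8), matrix(1, 16, 8))
  ge <- stop_function(image_volume(img), sigma = 1)
  edge_val <- min(ge[8, ])
  expect_lt(edge_val, 0.1)
  expect_equal(which.min(ge[8, ]) %in% 8:9, TRUE)
  expect_gt(ge[8, 2], 0.9)
})

test_that("posterior stop function dips where posteriors separate", {
  # smooth ramp between two plateaus: intermediate intensities at the
  # transition have ambiguous class posteriors (g near 1), plateaus are
  # confidently classified (g near 0)
  ramp <- matrix(rep(100 * plogis(seq(-10, 10, length.out = 24)),
                     each = 24), 24, 24)
  gp <- stop_function(image_volume(ramp), mode = "posterior", seed = 1)
  expect_true(all(gp > 0 & gp <= 1))
  expect_lt(mean(gp[, c(1:6, 19:24)]), mean(gp[, 12:13]))
})

test_that("curvature-only evolution shrinks a circle monotonically", {
  v <- image_volume(matrix(50, 48, 48) + matrix(rnorm(48^2, 0, 1e-3), 48))
  ff <- build_feature_field(v)
  init <- noduleseg:::init_to_mask(list(seed = c(24, 24), radius_mm = 8),
                                   c(48, 48), c(1, 1))
  phi <- noduleseg:::signed_distance(init, c(1, 1))
  st <- level_set_state(phi, c(1, 1))
  pars <- acm_params(lambda1 = 0, lambda2 = 0, gamma = 0, mu = 2, dt = 0.4)
  areas <- sum(st$phi >= 0)
  for (i in 1:60) {
    st <- evolve_step(st, ff, pars, u = 0.5, g = 1)
    areas <- c(areas, sum(st$phi >= 0))
  }
  expect_lt(areas[length(areas)], areas[1])
  expect_true(all(diff(areas) <= 2))  # never grows beyond reinit rounding
})

test_that("the data force moves the contour towards the matching population", {
  img <- cbind(matrix(0, 24, 12), matrix(100, 24, 12))
  vol <- image_volume(img)
  ff <- build_feature_field(vol)
  # initialize inside the bright half, offset from the true boundary
  init <- noduleseg:::init_to_mask(list(seed = c(12, 18), radius_mm = 4),
                                   c(24, 24), c(1, 1))
  seg <- suppressWarnings(
    segment_nodule(vol, init, acm_params(max_iter = 60, seed = 1)))
  truth <- array(FALSE, c(24, 24)); truth[, 13:24] <- TRUE
  expect_lt(jaccard_error(seg$mask$data, truth), 0.1)
})

test_that("narrow band updates touch a small fraction of the volume", {
  ph <- make_phantom(phantom_spec("solid_disc", size = 96, radius_mm = 12))
  ff <- build_feature_field(ph$volume)
  init <- noduleseg:::init_to_mask(list(seed = c(48, 48), radius_mm = 8),
                                   c(96, 96), c(1, 1))
  phi <- noduleseg:::signed_distance(init, c(1, 1))
  band <- sum(abs(phi) <= 3)
  expect_lt(band / prod(dim(phi)), 0.05)
})

test_that("segment_nodule is deterministic given the seed", {
  ph <- make_phantom(phantom_spec("ggo_blob", size = 48, radius_mm = 8,
                                  edge_sigma_mm = 2, inhomogeneity = 0.3,
                                  noise_sd = 8, seed = 5))
  run <- function() suppressWarnings(
    segment_nodule(ph$volume, init = list(seed = c(24, 24), radius_mm = 4),
                   params = acm_params(max_iter = 40, seed = 7)))
  a <- run(); b <- run()
  expect_identical(a$mask$data, b$mask$data)
  expect_identical(a$trace, b$trace)
})

test_that("an initialization on empty background collapses and is flagged", {
  img <- matrix(0, 48, 48); img[20:28, 20:28] <- 100
  vol <- image_volume(img + rnorm(48^2, 0, 1))
  seg <- suppressWarnings(
    segment_nodule(vol, init = list(seed = c(8, 40), radius_mm = 4),
                   params = acm_params(max_iter = 50, seed = 1)))
  expect_true(seg$collapsed || sum(seg$mask$data) < 30)
})

test_that("parenchyma pre-segmentation recovers the lung fields", {
  ph <- make_phantom(phantom_spec("chest_slice", size = 96, spacing = 3,
                                  ct_mode = TRUE, noise_sd = 20, seed = 4))
  pm <- parenchyma_mask(ph$volume)
  expect_gte(dice_coefficient(pm, ph$truth$lungs), 0.98)
  expect_error(parenchyma_mask(image_volume(matrix(-1000, 32, 32) +
                                              matrix(rnorm(1024), 32))),
               "lung")
})

test_that("closing mends a simulated juxta-pleural notch", {
  ph <- make_phantom(phantom_spec("chest_slice", size = 96, spacing = 3,
                                  ct_mode = TRUE, noise_sd = 10, seed = 4))
  img <- ph$volume$data
  # carve a notch: a body-intensity bump into the left lung boundary
  lung_idx <- which(ph$truth$lungs$data, arr.ind = TRUE)
  left <- lung_idx[lung_idx[, 1] < 48, ]
  notch_ctr <- left[which.min(left[, 1]), ]
  di <- abs(row(img) - notch_ctr[1]); dj <- abs(col(img) - notch_ctr[2])
  img[di <= 1 & dj <= 1] <- 40
  vol <- image_volume(img, spacing = c(3, 3))
  with_notch <- parenchyma_mask(vol)
  no_close <- tryCatch(parenchyma_mask(vol, close_radius_mm = 0.1),
                       error = function(e) NULL)
  expect_gte(dice_coefficient(with_notch, ph$truth$lungs), 0.97)
  if (!is.null(no_close)) {
    convdef <- function(m) sum(noduleseg:::fill_cavities(m$data)) - sum(m$data)
    expect_lte(convdef(with_notch), convdef(no_close) + 1)
  }
})
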