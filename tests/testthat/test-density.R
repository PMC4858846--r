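grid01 <- seq(0, 1, length.out = 512)

test_that("Parzen densities integrate to one and average kernels", {
  p <- parzen_density(0.5, sigma = 0.05, grid = grid01)
  expect_equal(trapz_num(p$grid, p$values), 1, tolerance = 1e-9)
  expect_lt(abs(p$grid[which.max(p$values)] - 0.5), 2 / 512)
  # identical samples give the single-kernel density
  pk <- parzen_density(rep(0.5, 17), sigma = 0.05, grid = grid01)
  expect_equal(pk$values, p$values)
  expect_error(parzen_density(numeric(0), 0.1, grid01), "sample")
  expect_error(parzen_density(0.5, -1, grid01), "positive")
})

test_that("Parzen estimate beats a histogram on a known mixture (MISE)", {
  set.seed(11)
  true_d <- function(x) 0.6 * dnorm(x, 0.3, 0.05) + 0.4 * dnorm(x, 0.7, 0.08)
  x <- c(rnorm(6000, 0.3, 0.05), rnorm(4000, 0.7, 0.08))
  sigma <- 0.02
  p <- parzen_density(x, sigma, grid01)
  ise_parzen <- trapz_num(grid01, (p$values - true_d(grid01))^2)
  # histogram density with bin width = sigma, evaluated on the same grid
  breaks <- seq(-0.2, 1.2, by = sigma)
  h <- hist(x, breaks = breaks, plot = FALSE)
  hd <- h$density[findInterval(grid01, breaks, all.inside = TRUE)]
  ise_hist <- trapz_num(grid01, (hd - true_d(grid01))^2)
  expect_lt(ise_parzen, ise_hist)
})

test_that("pdf_distance is a symmetric nonnegative metric on the grid", {
  p <- parzen_density(0.5, 0.05, grid01)
  expect_equal(pdf_distance(p, p), 0)
  expect_equal(pdf_distance(p, p, "l1_pdf"), 0)
  set.seed(3)
  for (i in 1:10) {
    a <- parzen_density(runif(5), 0.05, grid01)
    b <- parzen_density(runif(5), 0.05, grid01)
    c <- parzen_density(runif(5), 0.05, grid01)
    for (mode in c("wasserstein_cdf", "l1_pdf")) {
      dab <- pdf_distance(a, b, mode)
      expect_gte(dab, 0)
      expect_equal(dab, pdf_distance(b, a, mode))
      expect_lte(dab, pdf_distance(a, c, mode) + pdf_distance(c, b, mode) +
                   1e-12)
    }
  }
})

test_that("Wasserstein between near-deltas equals the centre distance", {
  a <- 0.25; b <- 0.65
  p <- parzen_density(a, 0.004, grid01)
  q <- parzen_density(b, 0.004, grid01)
  expect_equal(pdf_distance(p, q), abs(a - b), tolerance = 0.01)
})

test_that("L1 distance between disjoint unit boxes is 2", {
  v1 <- as.numeric(grid01 >= 0.1 & grid01 <= 0.3)
  v2 <- as.numeric(grid01 >= 0.6 & grid01 <= 0.8)
  p <- density_estimate(grid01, v1)
  q <- density_estimate(grid01, v2)
  expect_equal(pdf_distance(p, q, "l1_pdf"), 2, tolerance = 0.02)
})

test_that("Bhattacharyya coefficient hits its closed forms", {
  p <- parzen_density(0.5, 0.03, grid01)
  expect_equal(bhattacharyya_coefficient(p, p), 1)
  q <- parzen_density(0.1, 0.004, grid01)
  r <- parzen_density(0.9, 0.004, grid01)
  expect_equal(bhattacharyya_coefficient(q, r), 0, tolerance = 1e-6)
  # unit-variance Gaussian pair: B = exp(-(mu1-mu2)^2 / 8)
  gg <- seq(-8, 11, length.out = 1024)
  for (dmu in c(0.5, 1, 2, 3)) {
    pa <- density_estimate(gg, dnorm(gg, 0, 1))
    pb <- density_estimate(gg, dnorm(gg, dmu, 1))
    expect_equal(bhattacharyya_coefficient(pa, pb), exp(-dmu^2 / 8),
                 tolerance = 1e-3)
  }
})

test_that("densities on mismatched grids are rejected", {
  p <- parzen_density(0.5, 0.05, grid01)
  q <- parzen_density(0.5, 0.05, seq(0, 2, length.out = 512))
  expect_error(pdf_distance(p, q), "same")
  expect_error(bhattacharyya_coefficient(p, q), "same")
})

test_that("regional kernel estimates split a two-valued image", {
  img <- cbind(matrix(0, 16, 8), matrix(100, 16, 8))
  ff <- build_feature_field(image_volume(img))
  # deep split: the arctan Heaviside has heavy tails, so weights only
  # concentrate well away from the interface
  phi <- cbind(matrix(-60, 16, 8), matrix(60, 16, 8))
  reg <- regional_kernel_estimates(ff, phi, sigma = 0.02)
  expect_equal(trapz_num(reg$p_plus$grid, reg$p_plus$values), 1,
               tolerance = 1e-9)
  expect_equal(reg$a_minus + reg$a_plus, 256, tolerance = 1e-6)
  expect_lt(bhattacharyya_coefficient(reg$p_minus, reg$p_plus), 0.25)
  # constant image: both sides identical, B ~ 1
  ffc <- build_feature_field(image_volume(matrix(1, 16, 16)))
  regc <- regional_kernel_estimates(ffc, phi, sigma = 0.02)
  expect_gt(bhattacharyya_coefficient(regc$p_minus, regc$p_plus), 0.999)
  # one-sided phi is degenerate
  expect_error(regional_kernel_estimates(ff, phi * 0 + 3, sigma = 0.02),
               "degenerate")
})
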