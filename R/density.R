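# Parzen-window densities over the scalar feature-norm domain, and the
# distribution distances driving the local (Wasserstein) and global
# (Bhattacharyya) energy terms.

trapz_w <- function(grid) {
  n <- length(grid)
  w <- numeric(n)
  dg <- diff(grid)
  w[1] <- dg[1] / 2
  w[n] <- dg[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dg[-(n - 1)] + dg[-1]) / 2
  w
}

trapz <- function(grid, values) sum(trapz_w(grid) * values)

#' Construct a density estimate on an evaluation grid
#'
#' @param grid strictly increasing evaluation points.
#' @param values nonnegative density values; renormalized so the
#'   trapezoidal integral over `grid` is exactly 1.
#' @param bandwidth kernel bandwidth used to build the estimate (if any).
#' @return A `density_estimate` with fields `grid`, `values`, `bandwidth`.
#' @export
density_estimate <- function(grid, values, bandwidth = NA_real_) {
  grid <- as.numeric(grid); values <- as.numeric(values)
  if (length(grid) < 2 || any(diff(grid) <= 0))
    stop("`grid` must be strictly increasing with >= 2 points")
  if (length(values) != length(grid)) stop("grid/values length mismatch")
  if (any(values < -1e-12)) stop("density values must be nonnegative")
  values <- pmax(values, 0)
  z <- trapz(grid, values)
  if (z <= 0) stop("density has zero mass on the grid")
  structure(list(grid = grid, values = values / z, bandwidth = bandwidth),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat("<density_estimate> ", length(x$grid), " grid points on [",
      signif(min(x$grid), 4), ", ", signif(max(x$grid), 4),
      "], bandwidth ", signif(x$bandwidth, 4), "\n", sep = "")
  invisible(x)
}

silverman_bw <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.349
  a <- min(s, iqr)
  if (!is.finite(a) || a <= 0) a <- max(s, 1e-3, na.rm = TRUE)
  if (!is.finite(a) || a <= 0) a <- 1e-3
  0.9 * a * n^(-1 / 5)
}

default_grid <- function(upper = sqrt(5) * 1.05, n = 256L) {
  seq(0, upper, length.out = n)
}

#' Parzen-window density of scalar feature norms
#'
#' Kernel density estimate `P(tau) = (1/k) sum_x K(tau - ||O(x)||)` with a
#' Gaussian kernel of bandwidth `sigma`, evaluated on `grid` and
#' renormalized to unit trapezoidal integral on the finite grid.
#'
#' @param samples scalar feature norms (>= 1 value).
#' @param sigma kernel bandwidth (> 0); `NULL` uses Silverman's rule on
#'   the sample set.
#' @param grid evaluation points; defaults to 256 points spanning the
#'   normalized feature-norm domain \[0, 1.05 * sqrt(5)\].
#' @param weights optional nonnegative sample weights.
#' @return A [density_estimate].
#' @examples
#' p <- parzen_density(c(0.5), sigma = 0.1, grid = seq(0, 1, len = 256))
#' @export
parzen_density <- function(samples, sigma = NULL, grid = default_grid(),
                           weights = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("need at least one sample")
  sigma <- sigma %||% silverman_bw(samples)
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be positive")
  if (is.null(weights)) weights <- rep(1, length(samples))
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative with positive sum")
  weights <- weights / sum(weights)
  # column per sample, row per grid point
  vals <- stats::dnorm(outer(grid, samples, `-`), sd = sigma) %*% weights
  density_estimate(grid, as.numeric(vals), bandwidth = sigma)
}

check_shared_grid <- function(p, q) {
  if (!identical(length(p$grid), length(q$grid)) ||
      max(abs(p$grid - q$grid)) > 1e-12)
    stop("densities must share the same evaluation grid")
}

#' Distance between two densities on a shared grid
#'
#' Two readings of the local similarity distance are available:
#' `"wasserstein_cdf"` (default) is the 1D W1 distance, the integral of
#' the absolute difference of the cumulative distributions;
#' `"l1_pdf"` is the literal L1 distance between the density functions.
#' Both are symmetric, nonnegative, and zero iff the densities agree on
#' the grid.
#'
#' @param p,q [density_estimate] objects on the same grid.
#' @param mode `"wasserstein_cdf"` or `"l1_pdf"`.
#' @return Nonnegative distance.
#' @export
pdf_distance <- function(p, q, mode = c("wasserstein_cdf", "l1_pdf")) {
  mode <- match.arg(mode)
  check_shared_grid(p, q)
  w <- trapz_w(p$grid)
  if (mode == "l1_pdf") return(sum(w * abs(p$values - q$values)))
  cdf_p <- cumsum(w * p$values)
  cdf_q <- cumsum(w * q$values)
  sum(w * abs(cdf_p - cdf_q))
}

#' Bhattacharyya coefficient between two densities
#'
#' `B = integral sqrt(P(tau) Q(tau)) dtau`, the overlap of two
#' unit-integral densities: 0 means complete mismatch (disjoint
#' supports), 1 a complete match.
#'
#' @param p,q [density_estimate] objects on the same grid.
#' @param tol tolerance for the negativity check.
#' @return Coefficient in \[0, 1\].
#' @export
bhattacharyya_coefficient <- function(p, q, tol = 1e-9) {
  check_shared_grid(p, q)
  if (any(p$values < -tol) || any(q$values < -tol))
    stop("densities must be nonnegative")
  b <- trapz(p$grid, sqrt(pmax(p$values, 0) * pmax(q$values, 0)))
  min(max(b, 0), 1)
}

#' Regional kernel density estimates inside/outside the contour
#'
#' Estimates the feature-norm densities of the two sub-domains separated
#' by the level-set function: the outside density is weighted by
#' `H(-phi)`, the inside by `H(phi)` (smoothed Heaviside weights), each
#' normalized by the corresponding smoothed region size `A_-`, `A_+`.
#'
#' @param features a `feature_field` from [build_feature_field].
#' @param phi numeric array congruent with the field (level-set values,
#'   positive inside).
#' @param sigma Parzen bandwidth; `NULL` for Silverman's rule.
#' @param grid evaluation grid.
#' @param epsilon Heaviside smoothing width.
#' @param tol minimal smoothed region size for a side to be non-degenerate.
#' @return A `regional_densities` list: `p_minus`, `p_plus`
#'   ([density_estimate]), `a_minus`, `a_plus` (region sizes in voxels).
#' @export
regional_kernel_estimates <- function(features, phi, sigma = NULL,
                                      grid = default_grid(),
                                      epsilon = 1.5, tol = 1e-3) {
  stopifnot(inherits(features, "feature_field"))
  if (!identical(dim(phi), features$dim))
    stop("`phi` shape does not match the feature field")
  h_plus <- smoothed_heaviside(as.vector(phi), epsilon)
  h_minus <- 1 - h_plus
  a_plus <- sum(h_plus); a_minus <- sum(h_minus)
  if (!any(phi >= 0) || a_plus < tol)
    stop("degenerate inside region (A+ ~ 0)")
  if (!any(phi < 0) || a_minus < tol)
    stop("degenerate outside region (A- ~ 0)")
  norms <- feature_norms(features)
  sigma <- sigma %||% silverman_bw(norms)
  list(p_minus = parzen_density(norms, sigma, grid, weights = h_minus),
       p_plus = parzen_density(norms, sigma, grid, weights = h_plus),
       a_minus = a_minus, a_plus = a_plus)
}
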