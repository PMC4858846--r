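# Integrated active-contour engine: fuzzy membership, stop function,
# smoothed Heaviside/Dirac, narrow-band level-set evolution combining an
# edge term, the KNN-adaptive local Wasserstein term and the global
# Bhattacharyya term, plus parenchyma pre-segmentation.

#' Smoothed Heaviside and Dirac functions
#'
#' Arctan-based global-support regularizations:
#' `H_eps(t) = (1 + (2/pi) atan(t/eps)) / 2` and its derivative
#' `delta_eps(t) = eps / (pi (eps^2 + t^2))`.
#'
#' @param t numeric values (level-set values).
#' @param epsilon smoothing width (> 0).
#' @return Values in (0, 1) for the Heaviside, >= 0 for the Dirac.
#' @export
smoothed_heaviside <- function(t, epsilon = 1.5) {
  if (epsilon <= 0) stop("epsilon must be positive")
  0.5 * (1 + (2 / pi) * atan(t / epsilon))
}

#' @rdname smoothed_heaviside
#' @export
smoothed_dirac <- function(t, epsilon = 1.5) {
  if (epsilon <= 0) stop("epsilon must be positive")
  epsilon / (pi * (epsilon^2 + t^2))
}

#' Parameters of the integrated active-contour model
#'
#' Weights, numerical settings and narrow-band configuration of the
#' level-set evolution. None of these have canonical values; the defaults
#' were chosen on the synthetic phantoms and are all tunable.
#'
#' @param mu weight of the edge (geodesic curvature) term.
#' @param lambda1,lambda2 weights of the local-region similarity terms
#'   (inside / outside).
#' @param gamma weight of the global Bhattacharyya separation term.
#' @param m fuzzy-membership exponent (>= 1).
#' @param sigma_parzen Parzen bandwidth on the normalized feature-norm
#'   domain.
#' @param grid_n density evaluation grid size used inside the evolution.
#' @param dt explicit Euler time step.
#' @param max_iter iteration cap.
#' @param tol convergence threshold on the mean absolute level-set change
#'   over the band (mm); must hold for 3 consecutive iterations.
#' @param epsilon Heaviside/Dirac smoothing width (mm).
#' @param band_width narrow-band half-width in voxels.
#' @param reinit_every signed-distance reinitialization period.
#' @param r,k,K0,adaptive local-region settings (see
#'   [local_region_spec]); `NULL` derives r and k from the spacing.
#' @param use_fuzzy compute the fuzzy C-means membership (otherwise a
#'   constant membership `u_const` is used).
#' @param u_const constant membership fallback.
#' @param distance_mode local similarity distance:
#'   `"wasserstein_cdf"` or `"l1_pdf"`.
#' @param global_mode global region term: `"density"` (Bhattacharyya
#'   separation of the feature-norm densities) or `"two_phase"` (classic
#'   piecewise-constant two-phase competition on the normalized
#'   intensity, the Chan-Vese baseline).
#' @param stop_mode `"gradient"` or `"posterior"` stop function.
#' @param asm_window window side for the texture feature.
#' @param roi_margin_mm optional region-of-interest half-margin: the
#'   evolution runs on the initialization's bounding box expanded by
#'   this many mm (cropped to the volume) and the mask is embedded back.
#'   Keeps a nodule segmentation nodule-scale instead of tracking an
#'   attached vessel across the whole volume; `NULL` uses the full
#'   volume.
#' @param seed RNG seed (fuzzy clustering initialization).
#' @return An `acm_params` list.
#' @export
acm_params <- function(mu = 1, lambda1 = 20, lambda2 = 20, gamma = 1,
                       m = 2, sigma_parzen = 0.05, grid_n = 64L,
                       dt = 0.4, max_iter = 150L, tol = 2e-3,
                       epsilon = 1.5, band_width = 3L, reinit_every = 10L,
                       r = NULL, k = NULL, K0 = 4, adaptive = TRUE,
                       use_fuzzy = TRUE, u_const = 0.5,
                       distance_mode = c("wasserstein_cdf", "l1_pdf"),
                       global_mode = c("density", "two_phase"),
                       stop_mode = c("gradient", "posterior"),
                       asm_window = 5L, roi_margin_mm = NULL,
                       seed = 1L) {
  if (dt <= 0) stop("dt must be positive")
  if (m < 1) stop("m must be >= 1")
  if (lambda1 < 0 || lambda2 < 0 || mu < 0 || gamma < 0)
    stop("energy weights must be nonnegative")
  structure(list(mu = mu, lambda1 = lambda1, lambda2 = lambda2,
                 gamma = gamma, m = m, sigma_parzen = sigma_parzen,
                 grid_n = as.integer(grid_n), dt = dt,
                 max_iter = as.integer(max_iter), tol = tol,
                 epsilon = epsilon, band_width = as.integer(band_width),
                 reinit_every = as.integer(reinit_every),
                 r = r, k = k, K0 = K0, adaptive = adaptive,
                 use_fuzzy = use_fuzzy, u_const = u_const,
                 distance_mode = match.arg(distance_mode),
                 global_mode = match.arg(global_mode),
                 stop_mode = match.arg(stop_mode),
                 asm_window = as.integer(asm_window),
                 roi_margin_mm = roi_margin_mm,
                 seed = as.integer(seed)),
            class = "acm_params")
}

#' Fuzzy C-means membership of the nodule cluster
#'
#' Clusters the (intensity, texture-level) feature pair into 2 fuzzy
#' clusters and returns the per-voxel membership of the nodule cluster:
#' the cluster with higher mean membership over the initialization region
#' when one is given, otherwise the cluster with the brighter intensity
#' centre. Memberships over the clusters sum to 1 per voxel.
#'
#' @param features a `feature_field`.
#' @param m fuzziness exponent (> 1).
#' @param seed RNG seed for the cluster initialization.
#' @param init optional [binary_mask] (or logical array) marking the
#'   initial object region.
#' @return Array of memberships in \[0, 1\], shaped like the volume.
#' @export
fuzzy_membership <- function(features, m = 2, seed = 1L, init = NULL) {
  stopifnot(inherits(features, "feature_field"))
  x <- features$features[, c("intensity", "asm_level"), drop = FALSE]
  if (max(x[, 1]) - min(x[, 1]) < 1e-12 &&
      max(x[, 2]) - min(x[, 2]) < 1e-12)
    stop("degenerate constant features: disable the fuzzy term ",
         "(use_fuzzy = FALSE) or provide a non-constant volume")
  fit <- with_seed(seed, e1071::cmeans(x, centers = 2, m = max(m, 1.01),
                                       iter.max = 200, verbose = FALSE))
  memb <- fit$membership
  if (!is.null(init)) {
    im <- if (inherits(init, "binary_mask")) init$data else init
    sel <- as.vector(im)
    nodule <- which.max(colMeans(memb[sel, , drop = FALSE]))
  } else {
    nodule <- which.max(fit$centers[, "intensity"])
  }
  array(memb[, nodule], features$dim)
}

#' Stop function for the edge term
#'
#' `"gradient"` (default): `g = 1 / (1 + (|grad(G_sigma * I)| /
#' (eta * max|grad|))^2)` -- near 1 in flat regions, small on strong
#' edges; the gradient magnitude is scaled relative to its maximum so the
#' function is contrast-invariant. `"posterior"`: two intensity classes
#' are fit (fuzzy 2-means), and `g = 1 - |p(obj|I) - p(bg|I)|` under
#' equal priors, clamped into (0, 1].
#'
#' @param volume an [image_volume].
#' @param mode `"gradient"` or `"posterior"`.
#' @param sigma Gaussian pre-smoothing in voxels.
#' @param eta relative gradient scale of the gradient mode.
#' @param seed RNG seed for the posterior-mode clustering.
#' @return Array in (0, 1\] shaped like the volume.
#' @export
stop_function <- function(volume, mode = c("gradient", "posterior"),
                          sigma = 1, eta = 0.1, seed = 1L) {
  stopifnot(inherits(volume, "image_volume"))
  mode <- match.arg(mode)
  d <- dim(volume$data)
  if (mode == "gradient") {
    sm <- gauss_smooth(volume$data, sigma)
    gr <- gradient_cd(sm)  # voxel units
    gm <- sqrt(Reduce(`+`, lapply(gr, function(a) a^2)))
    mx <- max(gm)
    if (mx == 0) return(array(1, d))
    return(array(1 / (1 + (gm / (eta * mx))^2), d))
  }
  ints <- as.vector(volume$data)
  if (max(ints) - min(ints) < 1e-12) return(array(1, d))
  cl <- with_seed(seed, e1071::cmeans(matrix(ints, ncol = 1), centers = 2,
                                      m = 2, iter.max = 100))
  mu1 <- cl$centers[1]; mu2 <- cl$centers[2]
  w <- cl$membership
  sd1 <- sqrt(stats::weighted.mean((ints - mu1)^2, w[, 1]))
  sd2 <- sqrt(stats::weighted.mean((ints - mu2)^2, w[, 2]))
  sd1 <- max(sd1, 1e-6); sd2 <- max(sd2, 1e-6)
  l1 <- stats::dnorm(ints, mu1, sd1); l2 <- stats::dnorm(ints, mu2, sd2)
  post1 <- l1 / pmax(l1 + l2, 1e-300)
  g <- 1 - abs(2 * post1 - 1)
  array(pmax(g, 1e-3), d)
}

#' Level-set state of the evolving contour
#'
#' @param phi signed level-set array (positive inside), in mm.
#' @param spacing voxel spacing (mm per axis).
#' @param epsilon Heaviside/Dirac smoothing width.
#' @param band_width narrow-band half-width in voxels.
#' @return A `level_set_state`.
#' @export
level_set_state <- function(phi, spacing = rep(1, length(dim(phi))),
                            epsilon = 1.5, band_width = 3L) {
  if (!all(is.finite(phi))) stop("phi must be finite")
  structure(list(phi = phi, spacing = as.numeric(spacing),
                 epsilon = epsilon, band_width = as.integer(band_width),
                 iter = 0L, conv_count = 0L, mean_dphi = Inf,
                 n_flips = NA_integer_, energy = NA_real_),
            class = "level_set_state")
}

#' @export
print.level_set_state <- function(x, ...) {
  cat("<level_set_state> iter ", x$iter, ", inside ",
      sum(x$phi >= 0), " voxels, mean |dphi| ",
      signif(x$mean_dphi, 4), "\n", sep = "")
  invisible(x)
}

# Batched local Wasserstein terms for the band voxels: the per-voxel
# density P(v) (Parzen over the adaptive local region of v) is compared
# against the mean densities p1/p2 of the inside/outside sub-domains.
# Returns W1, W2 vectors (0 where the corresponding side mean is NULL).
band_local_distances <- function(band, cache, features, spec,
                                 sigma, grid, mode, p1, p2) {
  norms_all <- attr(cache, "norms")
  w <- trapz_w(grid)
  nB <- length(band)
  W1 <- numeric(nB); W2 <- numeric(nB)
  cdf_row <- function(vals) cumsum(w * vals)
  c1 <- if (!is.null(p1)) cdf_row(p1$values) else NULL
  c2 <- if (!is.null(p2)) cdf_row(p2$values) else NULL
  # bound the per-chunk kernel matrix: ~4e4 samples x grid points
  chunk <- max(1L, as.integer(4e4 / (pi * spec$r^2)))
  for (start in seq(1L, nB, by = chunk)) {
    ii <- start:min(start + chunk - 1L, nB)
    regions <- lapply(band[ii], function(v) region_of(cache, features,
                                                      spec, v))
    lens <- lengths(regions)
    samples <- unlist(regions, use.names = FALSE)
    grp <- rep(seq_along(regions), lens)
    K <- stats::dnorm(outer(norms_all[samples], grid, `-`), sd = sigma)
    P <- rowsum(K, grp)
    z <- as.vector(P %*% w)
    P <- P / pmax(z, 1e-300)
    if (mode == "l1_pdf") {
      if (!is.null(p1))
        W1[ii] <- as.vector(abs(P - rep(p1$values, each = nrow(P))) %*% w)
      if (!is.null(p2))
        W2[ii] <- as.vector(abs(P - rep(p2$values, each = nrow(P))) %*% w)
    } else {
      cP <- t(apply(P * rep(w, each = nrow(P)), 1, cumsum))
      if (nrow(P) == 1) cP <- matrix(cP, 1)
      if (!is.null(p1))
        W1[ii] <- as.vector(abs(cP - rep(c1, each = nrow(cP))) %*% w)
      if (!is.null(p2))
        W2[ii] <- as.vector(abs(cP - rep(c2, each = nrow(cP))) %*% w)
    }
  }
  list(W1 = W1, W2 = W2)
}

# Lazy per-voxel local-region cache (regions depend on features only).
new_region_cache <- function(features) {
  e <- new.env(parent = emptyenv())
  attr(e, "norms") <- feature_norms(features)
  e
}

region_of <- function(cache, features, spec, v_lin) {
  key <- as.character(v_lin)
  got <- cache[[key]]
  if (!is.null(got)) return(got)
  reg <- select_local_region(v_lin, features, spec)$idx
  cache[[key]] <- reg
  reg
}

# Geodesic curvature term div(g * grad(phi)/|grad(phi)|), central
# differences, |grad phi| regularized.
curvature_term <- function(phi, g, spacing) {
  gr <- gradient_cd(phi, spacing)
  mag <- sqrt(Reduce(`+`, lapply(gr, function(a) a^2))) + 1e-8
  div <- array(0, dim(phi))
  for (ax in seq_along(gr)) {
    comp <- g * gr[[ax]] / mag
    dp <- integer(length(dim(phi))); dp[ax] <- 1L
    dm <- -dp
    div <- div + (shift_arr(comp, dm) - shift_arr(comp, dp)) /
      (2 * spacing[ax])
  }
  div
}

#' One narrow-band evolution step of the integrated model
#'
#' Updates the level-set on its narrow band with the explicit Euler step
#' of the integrated flow: the smoothed Dirac times (edge curvature term
#' + local Wasserstein similarity terms weighted by the fuzzy membership
#' + the Bhattacharyya separation flow). The Bhattacharyya flow is the
#' variational descent direction of the overlap coefficient: with
#' `I+ = int K(tau - ||O||) sqrt(P-/P+) dtau` and `I-` its mirror,
#' `V = (B (1/A+ - 1/A-) - I+/A+ + I-/A-) / 2`.
#'
#' @param state a [level_set_state].
#' @param features a `feature_field`.
#' @param params an [acm_params].
#' @param locals region cache created internally on first use (pass the
#'   value returned in `attr(state, "locals")` between calls, or NULL).
#' @param u membership array (or scalar).
#' @param g stop-function array (or scalar).
#' @return The updated `level_set_state` (fields `mean_dphi`, `energy`,
#'   `iter` refreshed; reinitialized to a signed distance every
#'   `reinit_every` iterations).
#' @export
evolve_step <- function(state, features, params, locals = NULL,
                        u = 0.5, g = 1) {
  stopifnot(inherits(state, "level_set_state"),
            inherits(features, "feature_field"),
            inherits(params, "acm_params"))
  d <- features$dim
  sp <- state$spacing
  phi <- state$phi
  if (is.null(locals)) locals <- attr(state, "locals")
  if (is.null(locals)) locals <- new_region_cache(features)
  spec <- attr(locals, "spec")
  if (is.null(spec)) {
    spec <- local_region_spec(r = params$r, k = params$k, K0 = params$K0,
                              adaptive = params$adaptive,
                              pixel_spacing = min(sp[1:2]))
    attr(locals, "spec") <- spec
  }
  band_thr <- params$band_width * min(sp)
  band <- which(abs(phi) <= band_thr)
  if (length(band) == 0) stop("empty narrow band")
  grid <- default_grid(n = params$grid_n)
  w <- trapz_w(grid)
  norms_all <- attr(locals, "norms")
  eps <- params$epsilon

  # global region term. The regional densities use the hard inside
  # indicator: the arctan Heaviside's global tails would otherwise let a
  # large background contribute more mass to the inside density than the
  # inside itself when the regions are very unbalanced.
  h_plus <- as.numeric(as.vector(phi) >= 0)
  n_vox <- length(norms_all)
  # region sizes as domain fractions: keeps the global flow O(1) per
  # voxel independently of the image size
  a_plus <- sum(h_plus) / n_vox
  a_minus <- 1 - a_plus
  if (a_plus * n_vox < 1e-3 || a_minus * n_vox < 1e-3)
    stop("degenerate region: one side of the contour is empty")
  stride <- max(1L, ceiling(n_vox / 8192))
  sub <- seq(1L, n_vox, by = stride)
  bcoef <- NA_real_
  if (params$global_mode == "two_phase") {
    # piecewise-constant two-phase competition on normalized intensity
    ints <- features$features[, "intensity"]
    c1 <- sum(h_plus * ints) / sum(h_plus)
    c2 <- sum((1 - h_plus) * ints) / sum(1 - h_plus)
    force_global <- -(ints[band] - c1)^2 + (ints[band] - c2)^2
  } else {
    # Bhattacharyya separation flow of the feature-norm densities
    Ksub <- stats::dnorm(outer(grid, norms_all[sub], `-`),
                         sd = params$sigma_parzen)
    p_plus <- as.vector(Ksub %*% h_plus[sub])
    p_minus <- as.vector(Ksub %*% (1 - h_plus[sub]))
    zp <- sum(w * p_plus); zm <- sum(w * p_minus)
    p_plus <- if (zp > 0) p_plus / zp else rep(0, length(grid))
    p_minus <- if (zm > 0) p_minus / zm else rep(0, length(grid))
    bcoef <- sum(w * sqrt(pmax(p_plus * p_minus, 0)))
    floor_p <- 1e-8
    ratio_mp <- sqrt(pmax(p_minus, floor_p) / pmax(p_plus, floor_p))
    ratio_pm <- 1 / ratio_mp
    Kband <- stats::dnorm(outer(norms_all[band], grid, `-`),
                          sd = params$sigma_parzen)
    i_plus <- as.vector(Kband %*% (w * ratio_mp))
    i_minus <- as.vector(Kband %*% (w * ratio_pm))
    force_global <- 0.5 * (bcoef * (1 / a_plus - 1 / a_minus) -
                             i_plus / a_plus + i_minus / a_minus)
  }

  # local adaptive Wasserstein terms: per-voxel adaptive-region density
  # vs the mean densities of the inside/outside sub-domains (Eq. 8-9 style
  # means over {phi >= 0} and {phi < 0})
  if (params$lambda1 > 0 || params$lambda2 > 0) {
    side <- as.vector(phi)[sub] >= 0
    p1 <- if (any(side))
      parzen_density(norms_all[sub][side], params$sigma_parzen, grid)
    else NULL
    p2 <- if (any(!side))
      parzen_density(norms_all[sub][!side], params$sigma_parzen, grid)
    else NULL
    loc <- band_local_distances(band, locals, features, spec,
                                params$sigma_parzen, grid,
                                params$distance_mode, p1, p2)
  } else loc <- list(W1 = numeric(length(band)),
                     W2 = numeric(length(band)))

  u_band <- if (length(u) == 1) rep(u, length(band)) else as.vector(u)[band]
  g_arr <- if (length(g) == 1) array(g, d) else g
  div_term <- curvature_term(phi, g_arr, sp)
  delta <- smoothed_dirac(phi, eps)

  # fuzzy-gated region competition: including a voxel costs its local
  # mismatch with the inside density discounted by its nodule membership,
  # excluding it costs the outside mismatch discounted by (1 - u)
  force <- delta[band] *
    (params$mu * div_term[band] -
       params$lambda1 * (1 - u_band)^params$m * loc$W1 +
       params$lambda2 * u_band^params$m * loc$W2 +
       params$gamma * force_global)

  sign_before <- phi[band] >= 0
  # CFL-style clamp: a voxel moves at most ~half a voxel per iteration,
  # so the narrow band cannot be vacated between reinitializations
  dphi <- params$dt * force
  lim <- 0.45 * min(sp)
  dphi <- pmin(pmax(dphi, -lim), lim)
  phi[band] <- phi[band] + dphi
  state$iter <- state$iter + 1L
  state$mean_dphi <- mean(abs(dphi))
  state$n_flips <- sum(sign_before != (phi[band] >= 0))
  # converged when the level-set change is negligible or the mask has
  # been stable for a while (forces balanced at the boundary)
  state$conv_count <- if (state$mean_dphi < params$tol ||
                          state$n_flips == 0L)
    state$conv_count + 1L else 0L

  # cheap energy audit: edge + local (band) + global overlap
  h_band <- as.numeric(phi[band] >= 0)
  gr <- gradient_cd(phi, sp)
  mag <- sqrt(Reduce(`+`, lapply(gr, function(a) a^2)))
  e_edge <- params$mu * sum(delta * g_arr * mag)
  e_local <- sum(params$lambda1 * (1 - u_band)^params$m * h_band * loc$W1 +
                   params$lambda2 * u_band^params$m *
                   (1 - h_band) * loc$W2)
  state$energy <- e_edge + e_local +
    if (is.na(bcoef)) 0 else params$gamma * bcoef

  if (state$iter %% params$reinit_every == 0L)
    phi <- signed_distance(phi >= 0, sp)
  state$phi <- phi
  attr(state, "locals") <- locals
  state
}

#' Segment a nodule with the integrated active-contour model
#'
#' Full nodule segmentation: texture/intensity feature field, fuzzy
#' membership, stop function, then narrow-band evolution of the
#' integrated flow until the mean level-set change over the band stays
#' below `tol` for 3 consecutive iterations (or `max_iter`). The output
#' mask is the nonnegative region of the converged level-set.
#'
#' @param volume an [image_volume].
#' @param init initialization: a [binary_mask], a logical array, or a
#'   list `list(seed = c(i, j[, k]), radius_mm = ...)` rasterized as a
#'   disc/sphere.
#' @param params an [acm_params].
#' @param features optional precomputed `feature_field` (rebuilt
#'   otherwise).
#' @return A `nodule_seg` object: `mask` ([binary_mask] of the segmented
#'   nodule), `state` (final [level_set_state]), `trace` (per-iteration
#'   mean change and energy), `converged` flag, `params`.
#' @examples
#' \donttest{
#' ph <- make_phantom(phantom_spec("solid_disc", size = 48, radius_mm = 9))
#' seg <- segment_nodule(ph$volume,
#'                       init = list(seed = c(24, 24), radius_mm = 5),
#'                       params = acm_params(max_iter = 60))
#' jaccard_error(seg$mask, ph$truth$object)
#' }
#' @export
segment_nodule <- function(volume, init, params = acm_params(),
                           features = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$data)
  sp <- volume$spacing
  init_mask <- init_to_mask(init, d, sp)
  if (!any(init_mask)) stop("initialization does not intersect the volume")
  if (!is.null(params$roi_margin_mm)) {
    nd <- length(d)
    bb <- arrayInd(which(init_mask), d)
    lo <- hi <- integer(nd)
    for (ax in seq_len(nd)) {
      mar <- ceiling(params$roi_margin_mm / sp[ax])
      lo[ax] <- max(1L, min(bb[, ax]) - mar)
      hi[ax] <- min(d[ax], max(bb[, ax]) + mar)
    }
    idx <- lapply(seq_len(nd), function(ax) lo[ax]:hi[ax])
    sub_vol <- image_volume(do.call(`[`, c(list(volume$data), idx,
                                           list(drop = FALSE))), sp)
    sub_init <- do.call(`[`, c(list(init_mask), idx, list(drop = FALSE)))
    sub_params <- params
    sub_params$roi_margin_mm <- NULL
    fit <- segment_nodule(sub_vol, sub_init, sub_params)
    full <- array(FALSE, d)
    full <- do.call(`[<-`, c(list(full), idx, list(fit$mask$data)))
    fit$mask <- binary_mask(full, spacing = sp)
    fit$roi <- cbind(lo = lo, hi = hi)
    return(fit)
  }
  features <- features %||% build_feature_field(volume,
                                                asm_window = params$asm_window)
  u <- if (params$use_fuzzy)
    fuzzy_membership(features, m = params$m, seed = params$seed)
  else array(params$u_const, d)
  g <- stop_function(volume, mode = params$stop_mode, seed = params$seed)
  phi <- signed_distance(init_mask, sp)
  state <- level_set_state(phi, sp, params$epsilon, params$band_width)
  locals <- new_region_cache(features)
  state_prev <- state
  trace <- data.frame(iter = integer(), mean_dphi = numeric(),
                      energy = numeric(), inside = integer(),
                      n_flips = integer())
  converged <- FALSE
  conv_span <- max(3L, params$reinit_every + 2L)
  for (it in seq_len(params$max_iter)) {
    state <- tryCatch(
      evolve_step(state, features, params, locals, u = u, g = g),
      error = function(e) {
        warning("evolution stopped at iteration ", it, ": ",
                conditionMessage(e))
        NULL
      })
    if (is.null(state)) { state <- state_prev; break }
    state_prev <- state
    trace[it, ] <- list(state$iter, state$mean_dphi, state$energy,
                        sum(state$phi >= 0), state$n_flips)
    if (state$conv_count >= conv_span) { converged <- TRUE; break }
  }
  mask <- binary_mask(array(state$phi >= 0, d), spacing = sp)
  if (!converged)
    warning("active contour did not converge within max_iter = ",
            params$max_iter)
  # a collapsed or unsupported fit: (near-)empty mask, or a mask whose
  # voxels carry essentially no nodule membership (initialization placed
  # on plain background)
  mean_u <- if (any(mask$data)) mean(u[mask$data]) else 0
  collapsed <- sum(mask$data) < max(4, 0.1 * sum(init_mask)) ||
    (params$use_fuzzy && mean_u < 0.3)
  structure(list(mask = mask, state = state, trace = trace,
                 converged = converged, collapsed = collapsed,
                 membership = u, stop_field = g, params = params),
            class = "nodule_seg")
}

#' @export
print.nodule_seg <- function(x, ...) {
  cat("<nodule_seg> ", sum(x$mask$data), " voxels segmented in ",
      x$state$iter, " iterations (",
      if (x$converged) "converged" else "max_iter reached",
      if (x$collapsed) ", contour collapsed" else "", ")\n", sep = "")
  invisible(x)
}

#' @export
summary.nodule_seg <- function(object, ...) {
  cat("Integrated ACM segmentation\n")
  print(object)
  cat("  final mean |dphi|:", signif(object$state$mean_dphi, 4), "\n")
  cat("  final energy:     ", signif(object$state$energy, 5), "\n")
  invisible(object)
}

init_to_mask <- function(init, d, sp) {
  if (inherits(init, "binary_mask")) return(init$data)
  if (is.logical(init) && !is.null(dim(init))) return(init)
  if (is.list(init) && !is.null(init$seed)) {
    g <- coord_grids(d, sp)
    ctr <- (as.numeric(init$seed) - 1) * sp
    r2 <- Reduce(`+`, lapply(seq_along(g),
                             function(ax) (g[[ax]] - ctr[ax])^2))
    return(r2 <= (init$radius_mm %||% 3)^2)
  }
  stop("unsupported initialization: give a mask, logical array, or ",
       "list(seed=, radius_mm=)")
}

#' Lung parenchyma pre-segmentation
#'
#' Thresholding + morphology pipeline for CT slices: Otsu threshold on
#' the intensity histogram separates air-like from tissue-like voxels;
#' dark regions not connected to the image border are lung candidates;
#' morphological closing (disc scaled to ~6.3 mm physical radius) mends
#' juxta-pleural notches; cavities are filled; the two largest interior
#' components are kept.
#'
#' @param volume an [image_volume] (2D slice, or 3D processed slice-wise).
#' @param close_radius_mm physical closing radius in mm.
#' @return A [binary_mask] of the lung fields.
#' @export
parenchyma_mask <- function(volume, close_radius_mm = 6.3) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$data)
  nd <- length(d)
  if (nd == 3) {
    out <- array(FALSE, d)
    for (kk in seq_len(d[3])) {
      sl <- image_volume(volume$data[, , kk], volume$spacing[1:2])
      out[, , kk] <- tryCatch(parenchyma_mask(sl, close_radius_mm)$data,
                              error = function(e) array(FALSE, d[1:2]))
    }
    if (!any(out)) stop("no lung interior component found in any slice")
    return(binary_mask(out, spacing = volume$spacing))
  }
  if (diff(range(volume$data)) < 1e-9)
    stop("no lung interior component found (constant image)")
  th <- otsu_threshold(volume$data)
  dark <- volume$data < th
  if (all(dark) || !any(dark))
    stop("no lung interior component found (degenerate threshold)")
  # require a real air/tissue separation, not a split of pure noise
  contrast <- mean(volume$data[!dark]) - mean(volume$data[dark])
  spread <- max(stats::sd(volume$data[dark]), stats::sd(volume$data[!dark]))
  if (contrast < 3 * spread)
    stop("no lung interior component found (no air/tissue contrast)")
  interior <- dark & !flood_reachable(dark, border_mask(d) & dark)
  # drop speckle: a lung field occupies a non-trivial part of the slice
  min_voxels <- max(16, round(0.002 * prod(d)))
  lab0 <- label_components(interior)
  sizes <- tabulate(lab0[lab0 > 0])
  interior <- interior & array(lab0 %in% which(sizes >= min_voxels), d)
  if (!any(interior)) stop("no lung interior component found")
  r_px <- max(1L, round(close_radius_mm / min(volume$spacing)))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  closed <- EBImage::closing(EBImage::Image(interior * 1, dim = d),
                             brush)
  closed <- array(as.numeric(closed) > 0.5, d)
  closed <- fill_cavities(closed)
  lab <- label_components(closed)
  keep <- lab > 0 & lab <= 2  # two largest components (size-ordered)
  binary_mask(array(keep, d), spacing = volume$spacing)
}
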