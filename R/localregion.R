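# Adaptive selection of the per-voxel local domain for the local energy:
# a disc/ball neighbourhood is accepted whole when its k nearest feature
# neighbours are consistent with the rest (homogeneous region); otherwise
# only the KNN set is used, which keeps irrelevant populations out of the
# local densities near zigzag or inhomogeneous edges.

#' Upper bound on the local-region radius from pixel spacing
#'
#' Nodules above 8 mm must remain distinguishable inside the local region,
#' so the radius is capped at half that diameter expressed in voxels:
#' `r_max = floor((8/2) / spacing)`, at least 1.
#'
#' @param pixel_spacing in-plane pixel spacing in mm/voxel (> 0).
#' @return Integer radius bound in voxels.
#' @examples
#' radius_bound(0.5)  # 8
#' @export
radius_bound <- function(pixel_spacing) {
  if (any(pixel_spacing <= 0)) stop("pixel spacing must be positive")
  pmax(floor(4.0 / pixel_spacing), 1)
}

#' Upper bound on the neighbour count k from pixel spacing
#'
#' The KNN set must stay well inside the disc of the maximal radius:
#' `k_max = floor(pi * ((8/2)/spacing)^2 / K0)`, at least 1, with the
#' divisor constant `K0 = 4` selected on phantom nodules.
#'
#' @param pixel_spacing in-plane pixel spacing in mm/voxel (> 0).
#' @param K0 divisor constant (> 0, default 4).
#' @return Integer neighbour-count bound.
#' @examples
#' k_bound(0.5)  # 50
#' @export
k_bound <- function(pixel_spacing, K0 = 4) {
  if (any(pixel_spacing <= 0)) stop("pixel spacing must be positive")
  if (K0 <= 0) stop("K0 must be positive")
  pmax(floor(pi * (4.0 / pixel_spacing)^2 / K0), 1)
}

#' Specification of the adaptive local region
#'
#' @param r disc/ball radius in voxels (>= 1); `NULL` derives it from the
#'   spacing via [radius_bound] (as large as the bound allows).
#' @param k neighbour count; `NULL` derives it via [k_bound]. Always
#'   clamped below the neighbourhood size so the complement is nonempty.
#' @param K0 divisor constant for [k_bound].
#' @param adaptive if `FALSE` the full disc/ball is always used (fixed
#'   local region, for comparison runs).
#' @param pixel_spacing in-plane spacing used for the derivations.
#' @return A `local_region_spec`.
#' @export
local_region_spec <- function(r = NULL, k = NULL, K0 = 4, adaptive = TRUE,
                              pixel_spacing = 1) {
  r <- as.integer(r %||% radius_bound(pixel_spacing))
  k <- as.integer(k %||% min(k_bound(pixel_spacing, K0),
                             floor(pi * r^2 / K0)))
  if (r < 1) stop("radius must be >= 1 voxel")
  if (k < 1) stop("k must be >= 1")
  structure(list(r = r, k = k, K0 = K0, adaptive = adaptive),
            class = "local_region_spec")
}

# Voxel-offset template of the disc (2D) / spacing-scaled ball (3D) of
# radius r voxels, excluding the centre. Returns an integer offset matrix.
region_offsets <- function(r, nd, spacing = rep(1, nd)) {
  if (nd == 2) {
    rng <- -r:r
    off <- as.matrix(expand.grid(di = rng, dj = rng))
    keep <- off[, 1]^2 + off[, 2]^2 <= r^2
  } else {
    rz <- max(1L, round(r * spacing[1] / spacing[3]))
    off <- as.matrix(expand.grid(di = -r:r, dj = -r:r, dk = -rz:rz))
    keep <- (off[, 1] / r)^2 + (off[, 2] / r)^2 +
      (off[, 3] / max(rz, 1))^2 <= 1
  }
  off <- off[keep & rowSums(abs(off)) > 0, , drop = FALSE]
  storage.mode(off) <- "integer"
  off
}

# Linear indices of the clipped neighbourhood of voxel `v` (index vector).
neighbourhood_idx <- function(v, d, offsets) {
  nd <- length(d)
  pos <- sweep(offsets, 2, as.integer(v), `+`)
  ok <- rep(TRUE, nrow(pos))
  for (ax in seq_len(nd)) ok <- ok & pos[, ax] >= 1L & pos[, ax] <= d[ax]
  pos <- pos[ok, , drop = FALSE]
  if (nd == 2) (pos[, 2] - 1L) * d[1] + pos[, 1]
  else ((pos[, 3] - 1L) * d[2] + (pos[, 2] - 1L)) * d[1] + pos[, 1]
}

#' Adaptively select the local domain of a voxel
#'
#' Builds the disc/ball neighbourhood `R_L` of radius `r` around voxel
#' `v` (clipped to the volume), finds the `k` nearest neighbours `N_k` of
#' `O(v)` by normalized feature distance (ties broken by spatial distance
#' to `v`, then by index), and checks the acceptance condition: for every
#' voxel `x` of `R_L`, its distance to every member of `N_k` must not
#' exceed its distance to any member of the complement `N_c`. If the
#' condition holds the full `R_L` is the local domain (homogeneous
#' neighbourhood); otherwise the adaptive KNN set (plus the centre voxel)
#' is used.
#'
#' @param v voxel index vector (i, j\[, k\]), or a linear index.
#' @param features a `feature_field`.
#' @param spec a [local_region_spec].
#' @return List with `idx` (linear voxel indices of the selected domain,
#'   centre included), `accepted_full` (logical), `r_l` (linear indices of
#'   the full clipped neighbourhood).
#' @export
select_local_region <- function(v, features, spec) {
  stopifnot(inherits(features, "feature_field"),
            inherits(spec, "local_region_spec"))
  d <- features$dim
  nd <- length(d)
  if (length(v) == 1) v <- arrayInd(as.integer(v), d)[1, ]
  offs <- region_offsets(spec$r, nd, features$spacing)
  rl <- neighbourhood_idx(v, d, offs)
  if (length(rl) == 0) stop("empty neighbourhood after clipping")
  v_lin <- if (nd == 2) (v[2] - 1L) * d[1] + v[1]
  else ((v[3] - 1L) * d[2] + (v[2] - 1L)) * d[1] + v[1]
  if (!spec$adaptive)
    return(list(idx = c(v_lin, rl), accepted_full = TRUE, r_l = rl))
  k <- spec$k
  if (k > length(rl))
    stop("k (", k, ") exceeds clipped neighbourhood size (", length(rl), ")")
  if (k >= length(rl))  # complement would be empty: full region by default
    return(list(idx = c(v_lin, rl), accepted_full = TRUE, r_l = rl))
  fd <- feature_distance(features, rep(v_lin, length(rl)), rl)
  sp_pos <- arrayInd(rl, d)
  sp_d2 <- rowSums((sweep(sp_pos, 2, as.integer(v), `-`) *
                      rep(features$spacing, each = nrow(sp_pos)))^2)
  ord <- order(fd, sp_d2, rl)
  nk <- rl[ord[seq_len(k)]]
  nc <- rl[ord[(k + 1L):length(rl)]]
  # condition: for all x in R_L, max_y d(x, N_k) <= min_z d(x, N_c)
  all_x <- c(v_lin, rl)
  fx <- appearance_matrix(features, all_x)
  fk <- appearance_matrix(features, nk)
  fc <- appearance_matrix(features, nc)
  cross_max <- function(a, b) {
    # max over b of pairwise distances, per row of a
    d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
      outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
    sqrt(pmax(d2, 0))
  }
  dk <- cross_max(fx, fk)
  dc <- cross_max(fx, fc)
  ok <- all(apply(dk, 1, max) <= apply(dc, 1, min) + 1e-12)
  if (ok) list(idx = c(v_lin, rl), accepted_full = TRUE, r_l = rl)
  else list(idx = c(v_lin, nk), accepted_full = FALSE, r_l = rl)
}

#' Mean local densities on the two sides of the contour
#'
#' Splits a local domain by the sign of the level-set function and
#' returns the Parzen densities of the feature norms on each side:
#' `P1` from voxels with `phi >= 0` (inside), `P2` from `phi < 0`.
#' An empty side yields `NULL` (its similarity term is treated as 0 by
#' the caller).
#'
#' @param region linear voxel indices of the local domain.
#' @param phi level-set array congruent with the feature field.
#' @param features a `feature_field`.
#' @param sigma Parzen bandwidth.
#' @param grid evaluation grid.
#' @return List with `p1`, `p2` ([density_estimate] or `NULL`).
#' @export
local_density_means <- function(region, phi, features, sigma = 0.05,
                                grid = default_grid()) {
  if (length(region) == 0) stop("empty local region")
  norms <- feature_norms(features, region)
  side <- as.vector(phi)[region] >= 0
  p1 <- if (any(side)) parzen_density(norms[side], sigma, grid) else NULL
  p2 <- if (any(!side)) parzen_density(norms[!side], sigma, grid) else NULL
  list(p1 = p1, p2 = p2)
}
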