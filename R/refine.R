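# Juxta-vascular refinement: the nodule/vessel attachment collar is the
# (dilated) intersection of the vessel and nodule candidate masks; inside
# it, K-means on a (position, intensity, shape-index) feature vector
# separates blob-like nodule voxels from ridge-like vessel voxels. Voxels
# outside the collar are never touched.

dilate_mask <- function(m, r) {
  if (r <= 0) return(m)
  nd <- length(dim(m))
  offs <- all_neighbour_offsets(nd)
  for (i in seq_len(r)) {
    grown <- m
    for (j in seq_len(nrow(offs)))
      grown <- grown | shift_arr(m, offs[j, ])
    m <- grown
  }
  m
}

#' Refinement region from vessel and nodule candidates
#'
#' `S_r = dilate(S_c1) intersect dilate(S_c2)`: the collar where the
#' potential vessel region meets the potential nodule region. A 1-voxel
#' dilation (default) yields a workable collar when the two masks barely
#' touch; `dilation = 0` is the literal intersection. An empty result is
#' valid (nothing to refine).
#'
#' @param s_c1 vessel candidate [binary_mask].
#' @param s_c2 nodule candidate [binary_mask], congruent with `s_c1`.
#' @param dilation dilation radius in voxels (>= 0).
#' @return A [binary_mask] `S_r`.
#' @export
refinement_region <- function(s_c1, s_c2, dilation = 1L) {
  stopifnot(inherits(s_c1, "binary_mask"), inherits(s_c2, "binary_mask"))
  if (!identical(dim(s_c1$data), dim(s_c2$data)))
    stop("candidate masks are not congruent")
  r <- as.integer(dilation)
  sr <- dilate_mask(s_c1$data, r) & dilate_mask(s_c2$data, r)
  binary_mask(sr, spacing = s_c2$spacing, origin = s_c2$origin)
}

# Analytic ascending eigenvalues of a symmetric 3x3 (trigonometric form),
# vectorized over voxels.
sym3_eigenvalues <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detb <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- detb / 2 / pmax(p, 1e-300)^3
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e3 <- q + 2 * p * cos(phi)
  e1 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  flat <- p < 1e-300
  e1[flat] <- q[flat]; e2[flat] <- q[flat]; e3[flat] <- q[flat]
  list(min = e1, mid = e2, max = e3)
}

#' Volumetric shape index
#'
#' Curvature-derived local shape descriptor on the \[0, 1\] scale:
#' `SI = 1/2 - (1/pi) * arctan((k1 + k2) / (k1 - k2))` with principal
#' curvatures `k1 >= k2` taken as the extreme eigenvalues of the Hessian
#' of the Gaussian-smoothed intensity. Bright blobs (both curvatures
#' negative) map to 1 (cap), bright tubes to 0.75 (ridge), flat regions
#' to 0.5 (flagged undefined).
#'
#' @param volume an [image_volume].
#' @param scale Gaussian smoothing scale in voxels (> 0).
#' @param flat_tol curvature magnitude (relative to the volume maximum)
#'   below which a voxel counts as flat.
#' @return List with `si` (array in \[0, 1\]) and `defined` (logical
#'   array, FALSE where flat).
#' @export
shape_index <- function(volume, scale = 1.5, flat_tol = 1e-3) {
  stopifnot(inherits(volume, "image_volume"))
  if (scale <= 0) stop("scale must be positive")
  d <- dim(volume$data)
  nd <- length(d)
  sm <- gauss_smooth(volume$data, scale)
  sp <- volume$spacing
  gr <- gradient_cd(sm, sp)
  if (nd == 2) {
    hxx <- gradient_cd(gr[[1]], sp)[[1]]
    hxy <- gradient_cd(gr[[1]], sp)[[2]]
    hyy <- gradient_cd(gr[[2]], sp)[[2]]
    ev <- sym2_eigen(as.vector(hxx), as.vector(hxy), as.vector(hyy))
    k2 <- ev$s1; k1 <- ev$s2
  } else {
    h <- list()
    for (a in 1:3) {
      ga <- gradient_cd(gr[[a]], sp)
      for (b in a:3) h[[paste0(a, b)]] <- as.vector(ga[[b]])
    }
    ev <- sym3_eigenvalues(h[["11"]], h[["22"]], h[["33"]],
                           h[["12"]], h[["13"]], h[["23"]])
    k2 <- ev$min; k1 <- ev$max
  }
  mag <- pmax(abs(k1), abs(k2))
  thr <- flat_tol * max(mag, 1e-300)
  si <- rep(0.5, length(k1))
  defined <- mag > thr
  diffk <- k1 - k2
  umb <- defined & diffk <= thr
  # umbilic continuity: caps (both negative) -> 1, cups (both positive) -> 0
  si[umb & k1 < 0] <- 1
  si[umb & k2 > 0] <- 0
  reg <- defined & diffk > thr
  si[reg] <- 0.5 - atan((k1[reg] + k2[reg]) / diffk[reg]) / pi
  list(si = array(si, d), defined = array(defined, d))
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  first <- sample.int(n, 1)
  centers[1, ] <- x[first, ]
  d2 <- rowSums((x - rep(centers[1, ], each = n))^2)
  for (j in seq_len(k - 1)) {
    probs <- d2 / sum(d2)
    if (!all(is.finite(probs)) || sum(d2) <= 0)
      nxt <- sample.int(n, 1)
    else nxt <- sample.int(n, 1, prob = probs)
    centers[j + 1, ] <- x[nxt, ]
    d2 <- pmin(d2, rowSums((x - rep(centers[j + 1, ], each = n))^2))
  }
  centers
}

#' K-means refinement of the juxta-vascular attachment
#'
#' Clusters the voxels of the refinement region `S_r` on the normalized
#' feature vector (x, y, z, intensity, shape index) with K-means
#' (k-means++ seeding, 10 restarts, best inertia). The cluster with the
#' highest mean shape index (blob-like) is labelled nodule; the refined
#' mask keeps `S_c2` outside `S_r` unchanged and replaces `S_r` by its
#' nodule-labelled voxels, then retains the connected component(s)
#' attached to the nodule core. If `S_r` has fewer voxels than clusters,
#' refinement is skipped with a warning and `S_c2` is returned.
#'
#' @param s_r refinement region [binary_mask].
#' @param s_c2 nodule candidate [binary_mask].
#' @param volume the underlying [image_volume] (features are computed on
#'   it).
#' @param k_clusters number of clusters (default 2: nodule vs vessel).
#' @param si_scale shape-index smoothing scale (voxels).
#' @param seed RNG seed (clustering is deterministic given the seed).
#' @return A [binary_mask]: the refined nodule segmentation. The voxels
#'   changed relative to `s_c2` always lie inside `s_r`.
#' @export
cluster_refine <- function(s_r, s_c2, volume, k_clusters = 2L,
                           si_scale = 1.5, seed = 1L) {
  stopifnot(inherits(s_r, "binary_mask"), inherits(s_c2, "binary_mask"),
            inherits(volume, "image_volume"))
  d <- dim(volume$data)
  if (!identical(dim(s_r$data), d) || !identical(dim(s_c2$data), d))
    stop("masks are not congruent with the volume")
  idx <- which(s_r$data)
  if (length(idx) == 0) return(s_c2)
  if (length(idx) < k_clusters) {
    warning("refinement region smaller than k_clusters; skipping")
    return(s_c2)
  }
  si <- shape_index(volume, scale = si_scale)$si
  g <- coord_grids(d, volume$spacing)
  nd <- length(d)
  feats <- cbind(x = as.vector(g[[1]])[idx],
                 y = as.vector(g[[2]])[idx],
                 z = if (nd == 3) as.vector(g[[3]])[idx] else 0,
                 intensity = as.vector(volume$data)[idx],
                 si = as.vector(si)[idx])
  # min-max normalize each component over S_r
  feats <- apply(feats, 2, function(v) {
    rg <- max(v) - min(v)
    if (rg == 0) rep(0, length(v)) else (v - min(v)) / rg
  })
  km <- with_seed(seed, {
    best <- NULL
    for (rs in seq_len(10)) {
      ctr <- kmeanspp_centers(feats, k_clusters)
      fit <- suppressWarnings(stats::kmeans(feats, centers = ctr,
                                            iter.max = 50))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss)
        best <- fit
    }
    best
  })
  si_means <- vapply(seq_len(k_clusters), function(cl)
    mean(as.vector(si)[idx][km$cluster == cl]), numeric(1))
  nodule_cl <- which.max(si_means)
  refined <- s_c2$data & !s_r$data
  refined[idx[km$cluster == nodule_cl]] <- TRUE
  # keep components attached to the unrefined nodule core
  core <- s_c2$data & !s_r$data
  if (any(refined)) {
    lab <- label_components(refined)
    keep_labs <- unique(lab[core & refined])
    keep_labs <- keep_labs[keep_labs > 0]
    if (length(keep_labs) == 0) keep_labs <- 1  # largest component
    refined <- refined & array(lab %in% keep_labs, d)
  }
  stopifnot(all((refined != s_c2$data) <= s_r$data))  # locality contract
  binary_mask(refined, spacing = s_c2$spacing, origin = s_c2$origin)
}
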