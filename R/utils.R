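# Internal array helpers shared by all stages. Arrays are 2D or 3D, first
# index fastest (R column-major); spacing is mm per axis, same length as dim().

# Shift an array by `delta` voxels along each axis with replicate padding.
shift_arr <- function(a, delta) {
  d <- dim(a)
  idx <- lapply(seq_along(d), function(ax) {
    i <- seq_len(d[ax]) - delta[ax]
    pmin(pmax(i, 1L), d[ax])
  })
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

gauss_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing, sigma in voxels (scalar or per-axis vector).
gauss_smooth <- function(a, sigma) {
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  sigma <- rep_len(sigma, length(d))
  out <- a
  for (ax in seq_along(d)) {
    if (sigma[ax] <= 0) next
    k <- gauss_kernel1d(sigma[ax])
    h <- (length(k) - 1L) / 2L
    acc <- array(0, d)
    for (j in seq_along(k)) {
      delta <- integer(length(d))
      delta[ax] <- j - h - 1L
      acc <- acc + k[j] * shift_arr(out, delta)
    }
    out <- acc
  }
  out
}

# Central-difference gradient; returns list of arrays, one per axis.
gradient_cd <- function(a, spacing = rep(1, length(dim(a)))) {
  d <- dim(a)
  lapply(seq_along(d), function(ax) {
    dp <- integer(length(d)); dp[ax] <- 1L
    dm <- integer(length(d)); dm[ax] <- -1L
    (shift_arr(a, dm) - shift_arr(a, dp)) / (2 * spacing[ax])
  })
}

# Exact L1 (city-block) distance transform to the TRUE set of `target`,
# anisotropic weights = spacing. Sequential forward/backward sweeps per axis.
l1_distance <- function(target, spacing = rep(1, length(dim(target)))) {
  d <- dim(target)
  dist <- array(Inf, d)
  dist[target] <- 0
  nd <- length(d)
  slice_ref <- function(arr, ax, i) {
    idx <- rep(list(quote(expr = )), nd)
    idx[[ax]] <- i
    do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  slice_assign <- function(arr, ax, i, val) {
    idx <- rep(list(quote(expr = )), nd)
    idx[[ax]] <- i
    do.call(`[<-`, c(list(arr), idx, list(val)))
  }
  for (ax in seq_len(nd)) {
    w <- spacing[ax]
    for (i in 2:d[ax]) {
      v <- pmin(slice_ref(dist, ax, i), slice_ref(dist, ax, i - 1L) + w)
      dist <- slice_assign(dist, ax, i, v)
    }
    for (i in (d[ax] - 1L):1L) {
      v <- pmin(slice_ref(dist, ax, i), slice_ref(dist, ax, i + 1L) + w)
      dist <- slice_assign(dist, ax, i, v)
    }
  }
  dist
}

# Signed distance (positive inside) from a logical mask; interface placed
# half a voxel outside the foreground boundary.
signed_distance <- function(mask, spacing = rep(1, length(dim(mask)))) {
  if (!any(mask)) return(array(-l1_distance(!mask, spacing) - 0.5, dim(mask)))
  if (all(mask)) return(array(l1_distance(mask, spacing) + 0.5, dim(mask)))
  d_in <- l1_distance(!mask, spacing)   # distance of fg voxels to bg
  d_out <- l1_distance(mask, spacing)   # distance of bg voxels to fg
  sdf <- array(0, dim(mask))
  sdf[mask] <- d_in[mask] - 0.5 * min(spacing)
  sdf[!mask] <- -(d_out[!mask] - 0.5 * min(spacing))
  sdf
}

# Face-connected neighbour offsets (4 in 2D, 6 in 3D).
face_offsets <- function(nd) {
  out <- list()
  for (ax in seq_len(nd)) for (s in c(-1L, 1L)) {
    delta <- integer(nd); delta[ax] <- s
    out[[length(out) + 1L]] <- delta
  }
  out
}

# Flood reachable set: grow `seeds` within `allowed` by face connectivity.
flood_reachable <- function(allowed, seeds) {
  reach <- seeds & allowed
  offs <- face_offsets(length(dim(allowed)))
  repeat {
    grown <- reach
    for (delta in offs) grown <- grown | shift_arr(reach, delta)
    grown <- grown & allowed
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach
}

# Label face-connected components by min-index propagation; returns integer
# array with 0 background and labels renumbered 1..n by decreasing size.
label_components <- function(mask) {
  d <- dim(mask)
  full <- array(0, d)
  full[mask] <- seq_len(sum(mask))
  offs <- face_offsets(length(d))
  big <- sum(mask) + 1
  repeat {
    cur <- full
    cur[!mask] <- big
    m <- cur
    for (delta in offs) m <- pmin(m, shift_arr(cur, delta))
    new_full <- full
    new_full[mask] <- pmin(full[mask], m[mask])
    if (identical(new_full, full)) break
    full <- new_full
  }
  labs <- sort(unique(full[mask]))
  if (length(labs)) {
    sizes <- tabulate(match(full[mask], labs))
    ord <- order(sizes, decreasing = TRUE)
    remap <- integer(length(labs)); remap[ord] <- seq_along(labs)
    full[mask] <- remap[match(full[mask], labs)]
  }
  full
}

# Border voxels of an array domain.
border_mask <- function(d) {
  b <- array(FALSE, d)
  nd <- length(d)
  for (ax in seq_len(nd)) {
    idx <- rep(list(quote(expr = )), nd)
    idx[[ax]] <- c(1L, d[ax])
    b <- do.call(`[<-`, c(list(b), idx, list(TRUE)))
  }
  b
}

# Fill interior cavities (background not face-connected to the border).
fill_cavities <- function(mask) {
  bg <- !mask
  reach <- flood_reachable(bg, border_mask(dim(mask)) & bg)
  mask | (bg & !reach)
}

# Otsu threshold of a numeric array (histogram-based, via EBImage).
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  xs <- (as.vector(x) - rng[1]) / diff(rng)
  img <- EBImage::Image(xs, dim = c(length(xs), 1L))
  th <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  rng[1] + th * diff(rng)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
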