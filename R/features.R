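# Gray-level co-occurrence texture (angular second moment), its level
# quantization, and the per-voxel normalized multi-feature field
# O = (x, y, z, I, ASM-level) used by the density-based energies.

#' Gray-level co-occurrence matrix of an intensity window
#'
#' Counts ordered pixel pairs separated by the displacement
#' `offset = (dx, dy)` inside an M x N window whose intensities have been
#' quantized to `n_levels` gray levels, then normalizes by the number of
#' valid pair positions `(M - dx)(N - dy)` so entries sum to 1.
#'
#' @param window numeric matrix. If `quantized = FALSE` (default) the
#'   intensities are linearly binned into `n_levels` levels over `range`
#'   (defaults to the window's own range); if `TRUE` the window must
#'   already hold integers in `0..n_levels-1`.
#' @param offset integer pair `(dx, dy)`: dx is the displacement along
#'   samples (columns), dy along lines (rows); both >= 0, not both 0.
#' @param n_levels number of gray levels N_g (>= 2).
#' @param range intensity range used for linear binning.
#' @param quantized set when `window` is already level-quantized.
#' @return A `glcm` object: list with `matrix` (n_levels x n_levels,
#'   sums to 1), `offset`, `n_levels`, `window_shape`.
#' @examples
#' g <- compute_glcm(matrix(5, 8, 8), offset = c(1, 0), n_levels = 8)
#' compute_asm(g)  # 1: perfectly uniform window
#' @export
compute_glcm <- function(window, offset = c(1L, 0L), n_levels = 8L,
                         range = NULL, quantized = FALSE) {
  if (!is.matrix(window)) stop("`window` must be a matrix")
  n_levels <- as.integer(n_levels)
  if (n_levels < 2) stop("`n_levels` must be at least 2")
  dx <- as.integer(offset[1]); dy <- as.integer(offset[2])
  if (dx < 0 || dy < 0 || (dx == 0 && dy == 0))
    stop("offset components must be >= 0 and not both 0")
  M <- ncol(window)  # samples per line
  N <- nrow(window)  # lines
  if (M <= dx || N <= dy)
    stop("window (", N, "x", M, ") too small for offset (", dx, ",", dy, ")")
  nr <- nrow(window); nc <- ncol(window)
  if (quantized) {
    q <- window
    if (any(q != floor(q)) || any(q < 0) || any(q > n_levels - 1))
      stop("quantized window must hold integers in 0..n_levels-1")
  } else {
    rng <- range %||% base::range(window)
    if (diff(rng) == 0) {
      q <- matrix(0, nr, nc)
    } else {
      q <- floor((window - rng[1]) / diff(rng) * n_levels)
      q <- pmin(pmax(q, 0), n_levels - 1)
    }
  }
  rows <- seq_len(nr - dy); cols <- seq_len(nc - dx)
  from <- q[rows, cols, drop = FALSE]
  to <- q[rows + dy, cols + dx, drop = FALSE]
  counts <- table(factor(from, levels = 0:(n_levels - 1)),
                  factor(to, levels = 0:(n_levels - 1)))
  Q <- matrix(as.numeric(counts), n_levels, n_levels)
  # normalize by the pair-position count W = 1/((M-dx)(N-dy)); direct
  # division keeps the entries exact binary fractions where possible
  structure(list(matrix = Q / ((M - dx) * (N - dy)), offset = c(dx, dy),
                 n_levels = n_levels, window_shape = c(nr, nc)),
            class = "glcm")
}

#' Angular second moment of a normalized co-occurrence matrix
#'
#' `ASM = sum_mn P(m,n)^2`: 1 for a perfectly uniform window (single
#' nonzero entry) down to 1/R when all R occupied pair bins are
#' equiprobable. High ASM means smooth/uniform texture.
#'
#' @param glcm a `glcm` from [compute_glcm], or a normalized matrix.
#' @param tol allowed deviation of the entry sum from 1.
#' @return ASM in \[0, 1\].
#' @export
compute_asm <- function(glcm, tol = 1e-8) {
  P <- if (inherits(glcm, "glcm")) glcm$matrix else glcm
  if (any(P < -tol)) stop("co-occurrence matrix has negative entries")
  if (abs(sum(P) - 1) > max(tol, 1e-6))
    stop("co-occurrence matrix is not normalized (sum = ", sum(P), ")")
  sum(P^2)
}

#' Quantize an ASM value to its discrete level
#'
#' The texture feature entering the multi-feature vector is a 6-level
#' discretization of ASM: level 0 for (0, 0.15\], 1 for (0.15, 0.23\],
#' 2 for (0.23, 0.35\], 3 for (0.35, 0.50\], 4 for (0.50, 0.80\],
#' 5 for (0.80, 1\].
#'
#' @param asm numeric ASM values in \[0, 1\] (vectorized).
#' @param tol tolerance on the domain check.
#' @return Integer levels in 0..5.
#' @examples
#' quantize_asm_level(c(0.2212, 0.6403))  # 1, 4
#' @export
quantize_asm_level <- function(asm, tol = 1e-9) {
  if (any(asm < -tol | asm > 1 + tol))
    stop("ASM must lie in [0, 1]")
  asm <- pmin(pmax(asm, 0), 1)
  cuts <- c(0.15, 0.23, 0.35, 0.50, 0.80)
  lev <- integer(length(asm))
  for (cc in cuts) lev <- lev + as.integer(asm > cc)
  if (is.null(dim(asm))) lev else array(lev, dim(asm))
}

# Sliding-window ASM over one 2D slice: for every pixel, the ASM of the
# centred window x window patch (reflect-padded at edges), averaged over
# the requested co-occurrence offsets.
slice_asm <- function(slice, window, offsets, n_levels, rng) {
  M <- nrow(slice); N <- ncol(slice)
  if (diff(rng) == 0) return(matrix(1, M, N))
  q <- floor((slice - rng[1]) / diff(rng) * n_levels)
  q <- pmin(pmax(q, 0), n_levels - 1)
  h <- (window - 1L) %/% 2L
  ridx <- function(n) {
    i <- c(rev(seq_len(h)) + 1L, seq_len(n), n - seq_len(h))
    pmin(pmax(i, 1L), n)
  }
  qp <- q[ridx(M), ridx(N)]
  Mp <- nrow(qp); Np <- ncol(qp)
  acc <- matrix(0, M, N)
  nb2 <- n_levels^2
  for (off in offsets) {
    dx <- off[1]; dy <- off[2]
    n_pos <- (window - dx) * (window - dy)
    pc <- qp[seq_len(Mp - dy), seq_len(Np - dx), drop = FALSE] * n_levels +
      qp[seq_len(Mp - dy) + dy, seq_len(Np - dx) + dx, drop = FALSE] + 1L
    for (j in seq_len(N)) {
      cols <- j:(j + window - 1L - dx)
      for (i in seq_len(M)) {
        cnt <- tabulate(pc[i:(i + window - 1L - dy), cols], nb2)
        acc[i, j] <- acc[i, j] + sum((cnt / n_pos)^2)
      }
    }
  }
  acc / length(offsets)
}

#' Per-voxel multi-feature field O = (x, y, z, I, ASM-level)
#'
#' Computes the angular second moment on a centred window around every
#' voxel (2D in-plane for 3D volumes, averaged over the configured
#' offsets), quantizes it to its 6-level code, assembles the 5-component
#' feature vector (position, intensity, texture level) and min-max
#' normalizes every component to \[0, 1\] over the volume. The
#' normalization record is retained so feature distances are reproducible.
#'
#' @param volume an [image_volume].
#' @param asm_window odd window side for the co-occurrence matrix (>= 3).
#' @param asm_offsets list of `(dx, dy)` displacements, averaged.
#' @param n_levels gray levels for co-occurrence quantization.
#' @param intensity_range binning range; defaults to the volume range
#'   (for clinical CT use c(-1000, 400)).
#' @return A `feature_field`: list with `features` (matrix, one row per
#'   voxel, columns x, y, z, intensity, asm_level, all in \[0, 1\]),
#'   `asm` (raw ASM array), `asm_level` (integer array), `norm` (per
#'   component min/range), `dim`, `spacing`.
#' @export
build_feature_field <- function(volume, asm_window = 5L,
                                asm_offsets = list(c(1L, 0L), c(0L, 1L)),
                                n_levels = 8L, intensity_range = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  asm_window <- as.integer(asm_window)
  if (asm_window < 3L || asm_window %% 2L == 0L)
    stop("`asm_window` must be odd and >= 3")
  d <- dim(volume$data)
  nd <- length(d)
  rng <- intensity_range %||% range(volume$data)
  asm <- array(1, d)
  if (nd == 2) {
    asm[] <- slice_asm(volume$data, asm_window, asm_offsets, n_levels, rng)
  } else {
    for (k in seq_len(d[3]))
      asm[, , k] <- slice_asm(volume$data[, , k], asm_window, asm_offsets,
                              n_levels, rng)
  }
  lev <- quantize_asm_level(asm)
  g <- coord_grids(d, volume$spacing)
  comp <- list(x = as.vector(g[[1]]), y = as.vector(g[[2]]),
               z = if (nd == 3) as.vector(g[[3]]) else rep(0, prod(d)),
               intensity = as.vector(volume$data),
               asm_level = as.vector(lev))
  norm <- lapply(comp, function(v) {
    mn <- min(v); rg <- max(v) - mn
    list(min = mn, range = rg)
  })
  feats <- mapply(function(v, nr) {
    if (nr$range == 0) rep(0, length(v)) else (v - nr$min) / nr$range
  }, comp, norm)
  structure(list(features = feats, asm = asm,
                 asm_level = array(as.integer(lev), d),
                 norm = norm, dim = d, spacing = volume$spacing),
            class = "feature_field")
}

#' @export
print.feature_field <- function(x, ...) {
  cat("<feature_field> ", paste(x$dim, collapse = " x "),
      " voxels, ASM range [", signif(min(x$asm), 4), ", ",
      signif(max(x$asm), 4), "]\n", sep = "")
  invisible(x)
}

# Similarity metric between voxels for the KNN region selection and the
# scalar density feature: Euclidean on the normalized appearance
# components (intensity, texture level). Position components stay out so
# a homogeneous neighbourhood has all-zero distances and is accepted
# whole; spatial proximity enters only as the deterministic tie-break.
# The texture level is tempered (weight < 1) so that the norm cannot
# alias a dark uniform population with a bright textured one (the scalar
# norm is not injective; keeping intensity dominant preserves the
# intensity ordering through the compression).
similarity_cols <- c("intensity", "asm_level")
appearance_weights <- c(intensity = 1, asm_level = 0.5)

appearance_matrix <- function(field, idx = NULL) {
  f <- if (is.null(idx)) field$features[, similarity_cols, drop = FALSE]
  else field$features[idx, similarity_cols, drop = FALSE]
  f * rep(appearance_weights, each = nrow(f))
}

feature_distance <- function(field, i, j) {
  fi <- appearance_matrix(field, i)
  fj <- appearance_matrix(field, j)
  sqrt(rowSums((fi - fj)^2))
}

# Scalar feature norms ||O|| for given voxel linear indices. As with the
# similarity distance, the norm entering the Parzen densities is taken on
# the weighted appearance components: position components would add a
# broad spatial continuum to the norm distribution that swamps the
# intensity/texture separation between the two sides of the contour.
feature_norms <- function(field, idx = NULL) {
  sqrt(rowSums(appearance_matrix(field, idx)^2))
}
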