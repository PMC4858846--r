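# Synthetic phantoms with analytic ground truth. Every stage of the pipeline
# is exercised on these: GGO-like inhomogeneous soft-edged blobs, solid
# discs, zigzag-edged discs, Gaussian-profile vessel tubes, sphere-on-tube
# juxta-vascular composites, and a chest-like slice for parenchyma tests.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic phantom
#'
#' Geometry is given in mm and rasterized at `spacing`. Intensities are
#' unit-free by default (background 0, object 100); `ct_mode = TRUE` maps
#' them to CT-like HU (object -440, lung background -670), echoing solid
#' low-density nodule models inside lung-attenuation material.
#'
#' @param kind one of `"solid_disc"`, `"ggo_blob"`, `"zigzag_edge"`,
#'   `"vessel_tube"`, `"juxta_vascular"`, `"chest_slice"`.
#' @param size voxels per axis (scalar or vector); 2D kinds default 64,
#'   3D kinds default 40.
#' @param spacing mm per voxel (scalar or per-axis).
#' @param radius_mm object (disc/sphere) radius.
#' @param tube_radius_mm vessel tube radius (3D kinds).
#' @param intensity_object,intensity_background mean intensities.
#' @param edge_sigma_mm soft-edge width: intensity ramps from object to
#'   background over this distance (0 = hard edge).
#' @param inhomogeneity relative amplitude of the smooth multiplicative
#'   intensity-inhomogeneity field applied to the object (0 = none).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param zigzag_amp,zigzag_freq relative amplitude and angular frequency of
#'   the boundary perturbation for `"zigzag_edge"`.
#' @param ct_mode map intensities to CT-like HU values.
#' @param seed RNG seed; same spec + seed reproduces the phantom bit-exactly.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(kind = c("solid_disc", "ggo_blob", "zigzag_edge",
                                  "vessel_tube", "juxta_vascular",
                                  "chest_slice"),
                         size = NULL, spacing = 1, radius_mm = 10,
                         tube_radius_mm = 3,
                         intensity_object = 100, intensity_background = 0,
                         edge_sigma_mm = 0, inhomogeneity = 0,
                         noise_sd = 0, zigzag_amp = 0.25, zigzag_freq = 8,
                         ct_mode = FALSE, seed = 1L) {
  kind <- match.arg(kind)
  nd <- if (kind %in% c("vessel_tube", "juxta_vascular")) 3L else 2L
  size <- size %||% if (nd == 2L) 64L else 40L
  size <- rep_len(as.integer(size), nd)
  spacing <- rep_len(as.numeric(spacing), nd)
  if (any(size < 8)) stop("phantom size must be at least 8 voxels per axis")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (radius_mm <= 0 || tube_radius_mm <= 0) stop("radii must be positive")
  if (intensity_object == intensity_background)
    stop("object and background intensities must differ")
  if (ct_mode) {
    intensity_object <- -440
    intensity_background <- -670
  }
  ext <- size * spacing
  if (kind != "chest_slice" && 2 * radius_mm > 0.9 * min(ext))
    stop("object radius exceeds volume extent")
  structure(list(kind = kind, size = size, spacing = spacing,
                 radius_mm = radius_mm, tube_radius_mm = tube_radius_mm,
                 intensity_object = intensity_object,
                 intensity_background = intensity_background,
                 edge_sigma_mm = edge_sigma_mm,
                 inhomogeneity = inhomogeneity, noise_sd = noise_sd,
                 zigzag_amp = zigzag_amp, zigzag_freq = zigzag_freq,
                 ct_mode = ct_mode, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Physical coordinate grids (mm), one array per axis.
coord_grids <- function(size, spacing) {
  nd <- length(size)
  lapply(seq_len(nd), function(ax) {
    v <- (seq_len(size[ax]) - 1) * spacing[ax]
    per <- rep(1L, nd); per[ax] <- size[ax]
    array(rep(v, each = prod(size[seq_len(ax - 1L)])), size)
  })
}

# Soft coverage from a signed distance field (negative inside), ramp width w.
soft_coverage <- function(sd_field, w) {
  if (w <= 0) return((sd_field <= 0) * 1.0)
  pmin(pmax(0.5 - sd_field / w, 0), 1)
}

smooth_field <- function(size, scale_vox, seed) {
  with_seed(seed, {
    f <- array(stats::rnorm(prod(size)), size)
    f <- gauss_smooth(f, scale_vox)
    f / max(abs(f), 1e-12)
  })
}

#' Generate a synthetic phantom and its ground-truth masks
#'
#' Shapes are rasterized from analytic signed distances (soft edges over
#' `edge_sigma_mm`), the GGO blob gets a low-frequency multiplicative
#' inhomogeneity field, and Gaussian noise is added last. Truth masks come
#' from the analytic geometry before any noise.
#'
#' @param spec a [phantom_spec].
#' @return A list with `volume` ([image_volume]) and `truth`, a named list
#'   of [binary_mask] objects (always including `"object"`; composites add
#'   `"sphere"`, `"tube"`; chest slices add `"lungs"`, `"body"`).
#' @examples
#' ph <- make_phantom(phantom_spec("solid_disc", radius_mm = 10))
#' sum(ph$truth$object$data)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  size <- spec$size; spacing <- spec$spacing
  g <- coord_grids(size, spacing)
  ctr <- (size - 1) * spacing / 2
  ib <- spec$intensity_background
  io <- spec$intensity_object
  w_edge <- max(spec$edge_sigma_mm, 0)
  truth <- list()

  if (spec$kind %in% c("solid_disc", "ggo_blob", "zigzag_edge")) {
    r2 <- (g[[1]] - ctr[1])^2 + (g[[2]] - ctr[2])^2
    if (spec$kind == "zigzag_edge") {
      theta <- atan2(g[[2]] - ctr[2], g[[1]] - ctr[1])
      rb <- spec$radius_mm *
        (1 + spec$zigzag_amp * sin(spec$zigzag_freq * theta))
      sdist <- sqrt(r2) - rb
    } else {
      sdist <- sqrt(r2) - spec$radius_mm
    }
    cov <- soft_coverage(sdist, w_edge)
    img <- ib + (io - ib) * cov
    if (spec$kind == "ggo_blob" && spec$inhomogeneity > 0) {
      fld <- smooth_field(size, spec$radius_mm / 2 / mean(spacing),
                          spec$seed + 1L)
      img <- ib + (img - ib) * (1 + spec$inhomogeneity * fld)
    }
    truth$object <- sdist <= 0
  } else if (spec$kind == "vessel_tube") {
    # tube along the third axis through the centre, Gaussian cross-section
    rad2 <- (g[[1]] - ctr[1])^2 + (g[[2]] - ctr[2])^2
    rt <- spec$tube_radius_mm
    prof <- exp(-rad2 / (2 * (rt / 1.5)^2))
    img <- ib + (io - ib) * prof
    truth$object <- rad2 <= rt^2
  } else if (spec$kind == "juxta_vascular") {
    rt <- spec$tube_radius_mm; rs <- spec$radius_mm
    # tube along axis 3; sphere centre offset along axis 1 so it overlaps
    # the tube wall (centre-to-axis distance = rs + rt/2 < rs + rt)
    rad2_tube <- (g[[1]] - ctr[1])^2 + (g[[2]] - ctr[2])^2
    sph_ctr <- ctr + c(rs + rt / 2, 0, 0)
    rad2_sph <- (g[[1]] - sph_ctr[1])^2 + (g[[2]] - sph_ctr[2])^2 +
      (g[[3]] - sph_ctr[3])^2
    sd_tube <- sqrt(rad2_tube) - rt
    sd_sph <- sqrt(rad2_sph) - rs
    cov <- soft_coverage(pmin(sd_tube, sd_sph), w_edge)
    img <- ib + (io - ib) * cov
    if (spec$inhomogeneity > 0) {
      fld <- smooth_field(size, rs / 2 / mean(spacing), spec$seed + 1L)
      img <- ib + (img - ib) * (1 + spec$inhomogeneity * fld)
    }
    truth$tube <- sd_tube <= 0
    truth$sphere <- sd_sph <= 0
    truth$object <- truth$tube | truth$sphere
  } else if (spec$kind == "chest_slice") {
    # air background, bright body disc, two dark elliptical lung interiors
    ext <- size * spacing
    body_r <- 0.45 * min(ext)
    sd_body <- sqrt((g[[1]] - ctr[1])^2 + (g[[2]] - ctr[2])^2) - body_r
    lung_a <- 0.16 * ext[1]; lung_b <- 0.28 * ext[2]
    off <- 0.20 * ext[1]
    sd_l1 <- sqrt(((g[[1]] - (ctr[1] - off)) / lung_a)^2 +
                    ((g[[2]] - ctr[2]) / lung_b)^2) - 1
    sd_l2 <- sqrt(((g[[1]] - (ctr[1] + off)) / lung_a)^2 +
                    ((g[[2]] - ctr[2]) / lung_b)^2) - 1
    air <- if (spec$ct_mode) -1000 else -100
    body_i <- if (spec$ct_mode) 40 else 200
    lung_i <- if (spec$ct_mode) -850 else -50
    img <- array(air, size)
    img[sd_body <= 0] <- body_i
    lungs <- (sd_l1 <= 0) | (sd_l2 <= 0)
    img[lungs] <- lung_i
    truth$lungs <- lungs
    truth$body <- sd_body <= 0 & !lungs
    truth$object <- lungs
  }

  if (spec$noise_sd > 0)
    img <- img + with_seed(spec$seed,
                           array(stats::rnorm(prod(size), 0, spec$noise_sd),
                                 size))
  vol <- image_volume(img, spacing = spacing)
  truth <- lapply(truth, function(m)
    binary_mask(array(m, size), spacing = spacing))
  list(volume = vol, truth = truth, spec = spec)
}

#' Texture tiles with analytically ordered angular second moment
#'
#' Builds small intensity tiles whose texture uniformity is controlled by
#' construction: a constant tile (ASM = 1), a two-level stripe tile, a
#' shuffled four-level tile, and a uniform-random tile over all gray
#' levels (expected ASM near 1/N_g^2). The returned `order` gives the
#' expected strictly decreasing ASM ranking.
#'
#' @param tile side length in pixels (>= 4, default 8).
#' @param n_levels number of gray levels used by the random tile.
#' @param seed RNG seed.
#' @return List with `tiles` (named list of integer matrices with values in
#'   0..n_levels-1), `order` (names, expected decreasing ASM), `n_levels`.
#' @export
make_texture_tiles <- function(tile = 8L, n_levels = 8L, seed = 1L) {
  if (tile < 4) stop("tile must be at least 4 pixels")
  tiles <- with_seed(seed, list(
    constant = matrix(0L, tile, tile),
    stripes = matrix(rep_len(c(0L, 1L), tile * tile), tile, tile),
    shuffled4 = matrix(sample(rep_len(0:3, tile * tile)), tile, tile),
    random = matrix(sample(0:(n_levels - 1L), tile * tile, replace = TRUE),
                    tile, tile)
  ))
  list(tiles = tiles,
       order = c("constant", "stripes", "shuffled4", "random"),
       n_levels = as.integer(n_levels))
}
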