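#' Scalar image volume with physical spacing
#'
#' Container for a 2D slice or 3D volume of scalar intensities (Hounsfield
#' units for CT, arbitrary units for synthetic phantoms) together with the
#' physical voxel spacing in mm per axis and the physical coordinate of the
#' first voxel. All segmentation stages operate on this type.
#'
#' @param data numeric matrix (2D) or 3D array of finite intensities.
#' @param spacing positive numeric vector, mm per voxel along each axis.
#' @param origin physical coordinate of voxel (1,1\[,1\]); defaults to zeros.
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @examples
#' v <- image_volume(matrix(rnorm(64), 8, 8), spacing = c(0.7, 0.7))
#' dim(v$data)
#' @export
image_volume <- function(data, spacing = rep(1, length(dim(data))),
                         origin = rep(0, length(dim(data)))) {
  if (is.null(dim(data))) stop("`data` must be a matrix or 3D array")
  nd <- length(dim(data))
  if (!nd %in% 2:3) stop("`data` must have 2 or 3 axes, got ", nd)
  if (!all(is.finite(data))) stop("`data` must be finite everywhere")
  spacing <- as.numeric(spacing)
  if (length(spacing) != nd || any(spacing <= 0))
    stop("`spacing` must be ", nd, " positive values (mm/voxel)")
  origin <- as.numeric(origin)
  if (length(origin) != nd) stop("`origin` must have ", nd, " components")
  structure(list(data = array(as.numeric(data), dim(data)),
                 spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n  intensity range [", signif(min(x$data), 5), ", ",
      signif(max(x$data), 5), "]\n", sep = "")
  invisible(x)
}

#' Binary segmentation mask congruent with an image volume
#'
#' @param data logical (or 0/1) array, same shape as its source volume.
#' @param spacing,origin geometry inherited from the source volume.
#' @param reference optional `image_volume` whose geometry must match.
#' @return An object of class `binary_mask` with fields `data` (logical),
#'   `spacing`, `origin`.
#' @examples
#' m <- binary_mask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
#' sum(m$data)
#' @export
binary_mask <- function(data, spacing = rep(1, length(dim(data))),
                        origin = rep(0, length(dim(data))),
                        reference = NULL) {
  if (is.null(dim(data))) stop("`data` must be a matrix or 3D array")
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1))) stop("numeric mask values must be 0/1")
    data <- array(data > 0.5, dim(data))
  }
  if (!is.logical(data)) stop("`data` must be logical or 0/1 numeric")
  if (!is.null(reference)) {
    if (!identical(dim(data), dim(reference$data)))
      stop("mask shape ", paste(dim(data), collapse = "x"),
           " does not match reference volume ",
           paste(dim(reference$data), collapse = "x"))
    spacing <- reference$spacing
    origin <- reference$origin
  }
  structure(list(data = array(as.logical(data), dim(data)),
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$data), " foreground\n", sep = "")
  invisible(x)
}

#' Apply the CT rescale affine to stored values
#'
#' CT data is commonly stored as unsigned integers with a linear rescale
#' (slope, intercept) mapping to Hounsfield units: HU = slope * stored +
#' intercept.
#'
#' @param stored numeric stored values.
#' @param slope,intercept rescale parameters from the acquisition header.
#' @return Numeric values in HU.
#' @examples
#' apply_hu_rescale(1024, slope = 1, intercept = -1024)  # 0 HU (water)
#' @export
apply_hu_rescale <- function(stored, slope = 1, intercept = 0) {
  slope * stored + intercept
}

detect_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.png$", low)) return("png_stack")
  if (grepl("\\.rds$", low)) return("array")
  if (dir.exists(path)) return("dicom_dir")
  stop("cannot detect image format of '", path, "'")
}

#' Read an image volume from disk
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`; spacing from the header),
#' single PNG slices (treated as a 2D volume; 8/16-bit intensities scaled
#' back to integer gray levels; spacing from `default_spacing`), and
#' portable R arrays (`.rds` holding an `image_volume` or a plain array).
#' DICOM series are not supported and raise an informative error.
#'
#' @param path file path (or directory, rejected as DICOM).
#' @param format_hint optional, one of `"nifti"`, `"png_stack"`, `"array"`,
#'   `"dicom_dir"`; otherwise detected from the extension.
#' @param default_spacing spacing in mm used for formats without geometry
#'   metadata (PNG, plain arrays).
#' @return An [image_volume].
#' @export
read_volume <- function(path, format_hint = NULL,
                        default_spacing = NULL) {
  if (!file.exists(path)) stop("input path does not exist: '", path, "'")
  fmt <- format_hint %||% detect_format(path)
  switch(fmt,
    nifti = {
      img <- RNifti::readNifti(path)
      arr <- unclass(img)
      attributes(arr) <- list(dim = dim(img))
      sp <- RNifti::pixdim(img)[seq_along(dim(img))]
      image_volume(arr, spacing = sp)
    },
    png_stack = {
      px <- png::readPNG(path)
      if (length(dim(px)) == 3) px <- px[, , 1]  # first channel of RGB(A)
      sp <- default_spacing %||% c(1, 1)
      image_volume(round(px * 255), spacing = sp)
    },
    array = {
      obj <- readRDS(path)
      if (inherits(obj, "image_volume")) obj
      else image_volume(obj,
                        spacing = default_spacing %||%
                          rep(1, length(dim(obj))))
    },
    dicom_dir = stop("DICOM input is not supported; convert the series to ",
                     "NIfTI first (path: '", path, "')"),
    stop("unknown format '", fmt, "'")
  )
}

#' Write a binary mask to disk
#'
#' 2D masks are written as PNG with values \{0, 255\}; 3D masks as NIfTI
#' with values \{0, 1\} and the mask spacing in the header. Writing then
#' reading back reproduces the boolean grid exactly.
#'
#' @param mask a [binary_mask].
#' @param path destination ending in `.png` (2D) or `.nii`/`.nii.gz` (3D).
#' @param reference optional `image_volume` checked for congruent geometry.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path, reference = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.null(reference)) {
    if (!identical(dim(mask$data), dim(reference$data)))
      stop("mask shape does not match reference volume")
    if (max(abs(mask$spacing - reference$spacing)) > 1e-9)
      stop("mask spacing does not match reference volume")
  }
  nd <- length(dim(mask$data))
  low <- tolower(path)
  if (grepl("\\.png$", low)) {
    if (nd != 2) stop("PNG output requires a 2D mask")
    png::writePNG(array(as.numeric(mask$data), dim(mask$data)), path)
  } else if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- RNifti::asNifti(array(as.numeric(mask$data), dim(mask$data)))
    RNifti::pixdim(img) <- mask$spacing
    RNifti::writeNifti(img, path)
  } else stop("unsupported mask output format: '", path, "'")
  invisible(path)
}

#' Read a binary mask written by [write_mask]
#'
#' @param path PNG or NIfTI file.
#' @return A [binary_mask].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$data > max(v$data) / 2 & max(v$data) > 0,
              spacing = v$spacing, origin = v$origin)
}
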