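#' 3-D scalar image volume
#'
#' Lightweight container for a scalar volume on a regular 3-D grid: a CT
#' image in Hounsfield units or a dose distribution in Gy. The grid is
#' described by its voxel spacing (mm) and the world coordinate of the
#' centre of the first voxel.
#'
#' @param values numeric 3-D array.
#' @param spacing_mm positive numeric triple, voxel spacing in mm.
#' @param origin_mm numeric triple, world coordinate (mm) of the centre of
#'   voxel (1,1,1).
#' @param modality `"CT_HU"` or `"DOSE_GY"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0),
                         modality = c("DOSE_GY", "CT_HU")) {
  modality <- match.arg(modality)
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("'values' must be a 3-D array, got ", length(dim(values)), " dims")
  }
  if (any(!is.finite(values))) stop("image_volume values must all be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop("'spacing_mm' must be a positive numeric triple")
  }
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L) stop("'origin_mm' must be a numeric triple")
  structure(
    list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm,
         modality = modality),
    class = "image_volume"
  )
}

#' 3-D region-of-interest mask
#'
#' Boolean grid aligned to an [image_volume()]: lungs, GTV, or a derived
#' dose-thresholded sub-region.
#'
#' @param values logical 3-D array.
#' @inheritParams image_volume
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(values, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("'values' must be a 3-D array")
  if (!is.logical(values)) {
    if (!all(values %in% c(0, 1))) stop("mask values must be logical or 0/1")
    values <- array(as.logical(values), dim(values))
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop("'spacing_mm' must be a positive numeric triple")
  }
  structure(
    list(values = values, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "roi_mask"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              x$modality, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s voxels, %d in mask\n",
              paste(dim(x$values), collapse = "x"), sum(x$values)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' @export
dim.roi_mask <- function(x) dim(x$values)

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

stop_if_misaligned <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b)) {
    stop(what, " do not share grid geometry (shape/spacing/origin)")
  }
  invisible(TRUE)
}

#' Read / write volumes as NIfTI
#'
#' Volumes and masks are serialized as NIfTI-1 files with the voxel spacing
#' in `pixdim` and the origin in the affine translation. Masks are stored as
#' 0/1 integer grids.
#'
#' @param x an `image_volume` or `roi_mask`.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` and
#'   `read_mask()` return the reconstructed object.
#' @export
write_volume <- function(x, path) {
  vals <- if (inherits(x, "roi_mask")) array(as.integer(x$values), dim(x$values)) else x$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$spacing_mm
  # Diagonal RAS affine: voxel spacing on the diagonal, origin as translation.
  aff <- diag(c(x$spacing_mm, 1))
  aff[1:3, 4] <- x$origin_mm
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_grid <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  list(values = array(as.numeric(img), dim(img)[1:3]),
       spacing = abs(c(aff[1, 1], aff[2, 2], aff[3, 3])),
       origin = as.numeric(aff[1:3, 4]))
}

#' @rdname write_volume
#' @param modality modality tag to attach on read.
#' @export
read_volume <- function(path, modality = c("DOSE_GY", "CT_HU")) {
  g <- read_nifti_grid(path)
  image_volume(g$values, g$spacing, g$origin, match.arg(modality))
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  g <- read_nifti_grid(path)
  roi_mask(g$values != 0, g$spacing, g$origin)
}
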