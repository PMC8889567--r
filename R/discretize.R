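#' Intensity discretization rules for texture analysis
#'
#' Fixed-bin-size discretization of dose or CT intensities into integer
#' gray levels, the step preceding every texture-matrix construction.
#'
#' \describe{
#'   \item{dose}{bin width 1 Gy, left-closed bins anchored at 0 Gy:
#'     `level = floor(dose / 1) + 1`, capped at 100 levels, so doses are
#'     resolved up to the 100 Gy level.}
#'   \item{ct}{Hounsfield units are clamped to \[−1000, 100\], shifted by
#'     +1000 into \[0, 1100\] and binned with width 50:
#'     `level = floor(shifted / 50) + 1`; the top-of-range value 1100 maps
#'     to the top bin (level 23).}
#' }
#' Bins are left-closed, right-open: dose 0.4 Gy is level 1, dose 1.0 Gy
#' is level 2.
#'
#' @param modality `"dose"` or `"ct"`.
#' @param bin_width bin width (Gy for dose, shifted HU for CT).
#' @param max_levels level cap for dose discretization.
#' @param clamp low/high clamp for CT (HU).
#' @param shift additive shift applied to CT after clamping.
#' @return An object of class `discretization_spec`.
#' @export
discretization_spec <- function(modality = c("dose", "ct"),
                                bin_width = NULL, max_levels = NULL,
                                clamp = NULL, shift = NULL) {
  modality <- match.arg(modality)
  if (modality == "dose") {
    spec <- list(modality = "dose",
                 bin_width = bin_width %||% 1,
                 max_levels = max_levels %||% 100L,
                 clamp = NULL, shift = 0)
  } else {
    spec <- list(modality = "ct",
                 bin_width = bin_width %||% 50,
                 max_levels = NULL,
                 clamp = clamp %||% c(-1000, 100),
                 shift = shift %||% 1000)
    if (spec$clamp[1] >= spec$clamp[2]) stop("clamp low must be below clamp high")
  }
  if (spec$bin_width <= 0) stop("bin_width must be positive")
  structure(spec, class = "discretization_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discretize a volume into integer gray levels over an ROI
#'
#' @param v an [image_volume()].
#' @param roi non-empty [roi_mask()] aligned to `v`.
#' @param spec a [discretization_spec()].
#' @return A list with `levels` (integer 3-D array, `NA` outside the ROI)
#'   and `n_levels` (the highest level present).
#' @export
discretize <- function(v, roi, spec) {
  stopifnot(inherits(v, "image_volume"), inherits(roi, "roi_mask"),
            inherits(spec, "discretization_spec"))
  stop_if_misaligned(v, roi, "volume and ROI")
  if (!any(roi$values)) stop("ROI is empty; nothing to discretize")
  x <- v$values
  if (spec$modality == "ct") {
    x <- pmin(pmax(x, spec$clamp[1]), spec$clamp[2]) + spec$shift
  }
  lev <- floor(x / spec$bin_width) + 1
  if (!is.null(spec$max_levels)) lev <- pmin(lev, spec$max_levels)
  lev <- array(as.integer(lev), dim(x))
  lev[!roi$values] <- NA_integer_
  list(levels = lev, n_levels = max(lev, na.rm = TRUE))
}
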