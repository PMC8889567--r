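#' Per-fraction dose series
#'
#' An ordered list of per-fraction 3-D dose grids sharing one geometry,
#' as exported fraction-by-fraction from a treatment planning system. Each
#' fraction may deposit a different dose in each voxel (e.g. alternating
#' beam arrangements across fractions), which is exactly the situation the
#' voxel-wise EQD2 accumulation handles.
#'
#' @param fractions list of [image_volume()] objects with
#'   `modality = "DOSE_GY"`, one per delivered fraction.
#' @return An object of class `dose_series`.
#' @export
dose_series <- function(fractions) {
  if (!is.list(fractions) || length(fractions) < 1L) {
    stop("'fractions' must be a non-empty list of dose volumes")
  }
  for (i in seq_along(fractions)) {
    f <- fractions[[i]]
    if (!inherits(f, "image_volume")) stop("fraction ", i, " is not an image_volume")
    if (f$modality != "DOSE_GY") stop("fraction ", i, " is not a DOSE_GY volume")
    if (any(f$values < 0)) stop("fraction ", i, " contains negative dose voxels")
    if (i > 1L) stop_if_misaligned(fractions[[1]], f, paste0("fractions 1 and ", i))
  }
  structure(list(fractions = fractions), class = "dose_series")
}

#' @export
print.dose_series <- function(x, ...) {
  cat(sprintf("<dose_series> %d fractions of %s voxels\n",
              length(x$fractions), paste(dim(x$fractions[[1]]$values), collapse = "x")))
  invisible(x)
}

#' @export
length.dose_series <- function(x) length(x$fractions)

#' Accumulate a fraction series into a total physical dose
#'
#' Voxel-wise sum of the per-fraction doses, with no fractionation
#' correction.
#'
#' @param ds a [dose_series()].
#' @return An [image_volume()] of total physical dose (Gy).
#' @export
accumulate_physical <- function(ds) {
  stopifnot(inherits(ds, "dose_series"))
  total <- Reduce(`+`, lapply(ds$fractions, `[[`, "values"))
  g <- ds$fractions[[1]]
  image_volume(total, g$spacing_mm, g$origin_mm, "DOSE_GY")
}

#' EQD2 accumulation parameters
#'
#' @param alpha_beta tissue alpha/beta ratio in Gy; defaults to 3 Gy, the
#'   conventional value for late lung toxicity.
#' @return An object of class `eqd2_params`.
#' @export
eqd2_params <- function(alpha_beta = 3) {
  alpha_beta <- as.numeric(alpha_beta)
  if (length(alpha_beta) != 1L || !is.finite(alpha_beta) || alpha_beta <= 0) {
    stop("'alpha_beta' must be a single positive number (Gy)")
  }
  structure(list(alpha_beta = alpha_beta), class = "eqd2_params")
}

#' Accumulate a fraction series into equivalent dose in 2-Gy fractions
#'
#' Converts heterogeneous per-fraction, per-voxel doses into the equivalent
#' dose delivered in 2-Gy fractions under the linear-quadratic model. For
#' voxel k receiving dose \eqn{d_{i,k}} in fraction i of N:
#' \deqn{D_{EQD2}(k) = \sum_{i=1}^{N} \frac{d_{i,k} + d_{i,k}^2/(\alpha/\beta)}
#'       {1 + 2/(\alpha/\beta)}}
#' A fraction of exactly 2 Gy contributes exactly 2 Gy, so a uniform
#' 2-Gy-per-fraction course leaves the physical total unchanged; fractions
#' above 2 Gy are up-weighted (hypofractionation penalty) and fractions
#' below 2 Gy down-weighted. The transform is additive over fractions.
#'
#' @param ds a [dose_series()].
#' @param params an [eqd2_params()].
#' @return An [image_volume()] of EQD2 (Gy).
#' @export
accumulate_eqd2 <- function(ds, params = eqd2_params()) {
  stopifnot(inherits(ds, "dose_series"), inherits(params, "eqd2_params"))
  ab <- params$alpha_beta
  denom <- 1 + 2 / ab
  total <- 0
  for (f in ds$fractions) {
    d <- f$values
    if (any(d < 0)) stop("negative dose voxel in fraction series")
    total <- total + (d + d * d / ab) / denom
  }
  g <- ds$fractions[[1]]
  image_volume(total, g$spacing_mm, g$origin_mm, "DOSE_GY")
}
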