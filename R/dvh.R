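#' Dose-volume histogram features of a lung ROI
#'
#' Computes the 15 scalar DVH features used for pneumonitis risk modeling:
#' the mean lung dose (MLD) and the relative volumes Vx receiving a dose
#' strictly greater than x Gy, for x = 5, 10, ..., 70.
#'
#' Vx is a percentage of the ROI volume; the threshold is strict (`>`),
#' so a uniform 10 Gy ROI has V10 = 0 and V5 = 100. Many planning systems
#' report `>=` thresholds — results can differ there on exact-threshold
#' voxels. Absolute volumes in cm^3 are available via `absolute = TRUE`.
#'
#' @param dose [image_volume()] of total dose (Gy; typically the EQD2
#'   accumulation).
#' @param roi non-empty [roi_mask()] aligned to `dose`.
#' @param thresholds_gy numeric vector of Vx thresholds; default 5–70 Gy in
#'   5 Gy steps (14 values).
#' @param absolute if `TRUE`, Vx is reported in cm^3 instead of percent.
#' @return Named numeric vector: `MLD`, `V5`, ..., `V70` (15 values).
#' @export
compute_dvh <- function(dose, roi, thresholds_gy = seq(5, 70, by = 5),
                        absolute = FALSE) {
  stopifnot(inherits(dose, "image_volume"), inherits(roi, "roi_mask"))
  stop_if_misaligned(dose, roi, "dose and ROI")
  d <- dose$values[roi$values]
  if (length(d) == 0L) stop("ROI is empty; DVH undefined")
  vx <- vapply(thresholds_gy, function(x) sum(d > x), numeric(1))
  if (absolute) {
    voxel_cc <- prod(dose$spacing_mm) / 1000
    vx <- vx * voxel_cc
  } else {
    vx <- 100 * vx / length(d)
  }
  out <- c(mean(d), vx)
  names(out) <- c("MLD", paste0("V", thresholds_gy))
  out
}
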