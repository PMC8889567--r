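#' Derive the evaluation ROIs used for feature extraction
#'
#' Builds the lung evaluation ROI and its dose-thresholded sub-regions:
#' \describe{
#'   \item{`lung_eval`}{the bilateral lungs; for lung-cancer patients the
#'     gross tumor volume (GTV) is subtracted.}
#'   \item{`lung_gt10`, `lung_gt20`}{the part of `lung_eval` receiving a
#'     total dose strictly greater than 10 / 20 Gy — the CT radiomic
#'     extraction regions.}
#' }
#' Thresholds are strict (`>`), so a uniform 10 Gy lung has an empty
#' `lung_gt10`. By default the thresholded total is the accumulated
#' EQD2-corrected dose (the analysis dose); pass the physical total to
#' threshold on physical dose instead. An empty sub-ROI is allowed (the
#' corresponding radiomic block is reported missing downstream); an empty
#' `lung_eval` is an error.
#'
#' @param lung [roi_mask()] of the bilateral lungs.
#' @param gtv [roi_mask()] of the GTV, or `NULL` (esophageal patients).
#' @param total_dose [image_volume()] of accumulated total dose (Gy),
#'   aligned to the masks.
#' @param cancer_type `"esophageal"` or `"lung"`. For `"lung"` a GTV is
#'   required and subtracted from the lungs.
#' @return Named list of `roi_mask` objects:
#'   `lung_eval`, `lung_gt10`, `lung_gt20`.
#' @export
derive_rois <- function(lung, gtv = NULL, total_dose,
                        cancer_type = c("esophageal", "lung")) {
  cancer_type <- match.arg(cancer_type)
  stopifnot(inherits(lung, "roi_mask"), inherits(total_dose, "image_volume"))
  stop_if_misaligned(lung, total_dose, "lung mask and total dose")
  eval_vals <- lung$values
  if (cancer_type == "lung") {
    if (is.null(gtv)) stop("lung-cancer patients require a GTV mask")
    stop_if_misaligned(lung, gtv, "lung and GTV masks")
    eval_vals <- eval_vals & !gtv$values
  }
  if (!any(eval_vals)) stop("evaluation lung ROI is empty")
  mk <- function(v) roi_mask(v, lung$spacing_mm, lung$origin_mm)
  gt10 <- eval_vals & (total_dose$values > 10)
  gt20 <- eval_vals & (total_dose$values > 20)
  for (nm in c("gt10", "gt20")) {
    m <- if (nm == "gt10") gt10 else gt20
    if (!any(m)) {
      warning("sub-ROI lung_", nm, " is empty; radiomic features for it will be missing",
              call. = FALSE)
    }
  }
  list(lung_eval = mk(eval_vals), lung_gt10 = mk(gt10), lung_gt20 = mk(gt20))
}

#' Write derived ROIs as NIfTI files with a JSON index
#'
#' @param rois named list of [roi_mask()] from [derive_rois()].
#' @param directory output directory (created if needed).
#' @return Path of the JSON index, listing each ROI name, file and voxel
#'   count.
#' @export
write_rois <- function(rois, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  idx <- lapply(names(rois), function(nm) {
    path <- file.path(directory, paste0(nm, ".nii.gz"))
    write_volume(rois[[nm]], path)
    list(name = nm, path = path, n_voxels = sum(rois[[nm]]$values))
  })
  ipath <- file.path(directory, "rois.json")
  jsonlite::write_json(idx, ipath, auto_unbox = TRUE)
  ipath
}
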