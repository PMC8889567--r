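#' Extraction configuration
#'
#' Controls how raw patient grids become the 249-feature row: the dose
#' representation (EQD2-corrected by default, physical total optionally),
#' the tissue alpha/beta, the analysis voxel spacing (1.5 mm isotropic by
#' default; `NULL` extracts on the native grid), and the discretization
#' rules for dose and CT.
#'
#' @param alpha_beta alpha/beta ratio (Gy) for the EQD2 accumulation.
#' @param dose_mode `"eqd2"` or `"physical"` total dose; used both for the
#'   DVH/dosiomic dose and for the >10 / >20 Gy radiomic sub-ROI thresholds.
#' @param target_spacing_mm isotropic analysis spacing in mm, or `NULL` to
#'   stay on the native grid.
#' @param dose_disc,ct_disc [discretization_spec()] objects.
#' @return An object of class `extract_config`.
#' @export
extract_config <- function(alpha_beta = 3, dose_mode = c("eqd2", "physical"),
                           target_spacing_mm = 1.5,
                           dose_disc = discretization_spec("dose"),
                           ct_disc = discretization_spec("ct")) {
  dose_mode <- match.arg(dose_mode)
  structure(list(alpha_beta = alpha_beta, dose_mode = dose_mode,
                 target_spacing_mm = target_spacing_mm,
                 dose_disc = dose_disc, ct_disc = ct_disc),
            class = "extract_config")
}

#' Extract the 249-feature row of one patient
#'
#' Accumulates the fraction series into the analysis total dose, resamples
#' dose and CT (cubic) and masks (nearest) to the analysis grid, derives
#' the lung ROIs, and computes 15 DVH features, 78 dosiomic features (dose
#' texture in the evaluation lungs) and 2 x 78 radiomic features (CT
#' texture in the >10 Gy and >20 Gy lung sub-ROIs). Radiomic blocks whose
#' sub-ROI has fewer than 2 voxels are returned as `NA`.
#'
#' @param patient a `phantom_patient` (or any list with the same fields).
#' @param config an [extract_config()].
#' @return Named numeric vector of 249 features.
#' @export
extract_patient_features <- function(patient, config = extract_config()) {
  ds <- patient$fraction_doses
  total <- if (config$dose_mode == "eqd2") {
    accumulate_eqd2(ds, eqd2_params(config$alpha_beta))
  } else {
    accumulate_physical(ds)
  }
  ct <- patient$ct
  lung <- patient$lung_mask
  gtv <- patient$gtv_mask
  if (!is.null(config$target_spacing_mm)) {
    total <- resample_volume(total, config$target_spacing_mm, "bspline")
    total$values[total$values < 0] <- 0  # clip spline undershoot
    ct <- resample_volume(ct, config$target_spacing_mm, "bspline")
    lung <- resample_volume(lung, config$target_spacing_mm, "nearest")
    if (!is.null(gtv)) gtv <- resample_volume(gtv, config$target_spacing_mm, "nearest")
  }
  rois <- suppressWarnings(
    derive_rois(lung, gtv, total, patient$cancer_type)
  )

  dvh <- compute_dvh(total, rois$lung_eval)
  dos <- compute_features(total, rois$lung_eval, config$dose_disc)
  names(dos) <- paste0("dosiomic__lung__", names(dos))

  rad <- unlist(lapply(c("lung_gt10", "lung_gt20"), function(ctx) {
    roi <- rois[[ctx]]
    fe <- if (sum(roi$values) >= 2L) {
      compute_features(ct, roi, config$ct_disc)
    } else {
      stats::setNames(rep(NA_real_, 78L), feature_catalog())
    }
    stats::setNames(fe, paste0("radiomic__", ctx, "__", names(fe)))
  }))
  c(dvh, dos, rad)
}

#' Extract the feature table of a whole cohort
#'
#' @param patients list of `phantom_patient` objects.
#' @param config an [extract_config()].
#' @param verbose narrate progress every 20 patients.
#' @return A `data.frame` with columns `patient_id`, `cancer_type`,
#'   `rp_grade`, `label` (positive RP outcome per the cohort's grading
#'   rule) followed by the 249 feature columns. Feature groups are
#'   recoverable from the column names via [feature_groups()].
#' @export
extract_cohort_features <- function(patients, config = extract_config(),
                                    verbose = FALSE) {
  rows <- lapply(seq_along(patients), function(i) {
    if (verbose && i %% 20 == 0) message("  extracted ", i, "/", length(patients))
    extract_patient_features(patients[[i]], config)
  })
  feats <- do.call(rbind, rows)
  meta <- data.frame(
    patient_id = vapply(patients, `[[`, character(1), "patient_id"),
    cancer_type = vapply(patients, `[[`, character(1), "cancer_type"),
    rp_grade = vapply(patients, `[[`, integer(1), "rp_grade"),
    label = rp_labels(patients),
    stringsAsFactors = FALSE
  )
  cbind(meta, as.data.frame(feats, check.names = FALSE))
}

#' Feature-group tags of a feature table
#'
#' Groups are encoded in the column names: `MLD`/`Vx` columns are DVH
#' features; `dosiomic__*` and `radiomic__*` columns carry their group as
#' prefix.
#'
#' @param table a feature table from [extract_cohort_features()], or a
#'   character vector of column names.
#' @return Named character vector mapping each feature column to
#'   `"DVH"`, `"dosiomic"` or `"radiomic"`; non-feature columns omitted.
#' @export
feature_groups <- function(table) {
  nms <- if (is.character(table)) table else colnames(table)
  grp <- rep(NA_character_, length(nms))
  grp[grepl("^(MLD|V[0-9]+)$", nms)] <- "DVH"
  grp[startsWith(nms, "dosiomic__")] <- "dosiomic"
  grp[startsWith(nms, "radiomic__")] <- "radiomic"
  stats::setNames(grp, nms)[!is.na(grp)]
}

#' @rdname feature_groups
#' @param group one of `"DVH"`, `"dosiomic"`, `"radiomic"`.
#' @export
feature_columns <- function(table, group) {
  g <- feature_groups(table)
  names(g)[g == group]
}
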