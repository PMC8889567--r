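#' Specification of a synthetic phantom cohort
#'
#' Describes a cohort of schematic thorax phantoms used to exercise the
#' pneumonitis pipeline end to end: each patient gets a CT volume with a
#' soft-tissue background and two ellipsoidal low-density lungs, a series
#' of per-fraction beam-like dose grids, lung (and, for lung cancer, GTV)
#' masks, and an RP grade drawn from a logistic outcome model with planted
#' dose and heterogeneity effects.
#'
#' The outcome model is
#' `logit P(RP+) = intercept + effect_mld * MLD + effect_texture * z(h) + e`,
#' where MLD is the mean lung EQD2 in Gy, `z(h)` is the cohort-standardized
#' planted heterogeneity score — the within-lung variance of the
#' discretized CT, driven by the same latent factor as the dose texture,
#' so it is visible to texture features but not to the dose-volume
#' histogram — and `e ~ N(0, noise_sd)`. The intercept is
#' calibrated numerically so the expected prevalence matches
#' `target_prevalence`.
#'
#' Positive esophageal patients are labeled grade 1 (majority) or grade 2;
#' positive lung-cancer patients grade 2 (majority) or grade 3, mirroring
#' the grade mix of typical clinical series: in the emulated study the
#' esophageal cohort is 62% positive at grade >= 1 and the lung cohort 17%
#' positive at grade >= 2.
#'
#' @param n_patients number of phantoms.
#' @param cancer_type `"esophageal"` or `"lung"`.
#' @param target_prevalence expected positive fraction, in (0, 1).
#' @param grid_shape integer triple of voxel counts (all >= 8).
#' @param voxel_spacing_mm positive spacing triple (mm).
#' @param n_fractions_range integer interval for per-patient fraction counts.
#' @param effect_mld planted log-odds per Gy of mean lung dose.
#' @param effect_texture planted log-odds per SD of the heterogeneity score.
#' @param noise_sd SD of the latent logit noise.
#' @param seed integer RNG seed; the cohort is bit-reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        cancer_type = c("esophageal", "lung"),
                        target_prevalence = NULL,
                        grid_shape = c(32L, 32L, 24L),
                        voxel_spacing_mm = c(3, 3, 3),
                        n_fractions_range = c(25L, 30L),
                        effect_mld = 0.15,
                        effect_texture = 0.8,
                        noise_sd = 0.5,
                        seed = 1L) {
  cancer_type <- match.arg(cancer_type)
  if (is.null(target_prevalence)) {
    target_prevalence <- if (cancer_type == "esophageal") 0.62 else 0.17
  }
  stopifnot(n_patients >= 1, target_prevalence > 0, target_prevalence < 1,
            length(grid_shape) == 3, all(grid_shape >= 8),
            length(voxel_spacing_mm) == 3, all(voxel_spacing_mm > 0),
            length(n_fractions_range) == 2, n_fractions_range[1] >= 1,
            n_fractions_range[2] >= n_fractions_range[1],
            noise_sd >= 0)
  structure(list(
    n_patients = as.integer(n_patients), cancer_type = cancer_type,
    target_prevalence = target_prevalence,
    grid_shape = as.integer(grid_shape),
    voxel_spacing_mm = as.numeric(voxel_spacing_mm),
    n_fractions_range = as.integer(n_fractions_range),
    effect_mld = effect_mld, effect_texture = effect_texture,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Ellipsoid membership on the voxel grid; centre/semiaxes in voxel units.
ellipsoid_mask <- function(shape, centre, semi) {
  x <- seq_len(shape[1]); y <- seq_len(shape[2]); z <- seq_len(shape[3])
  dx2 <- ((x - centre[1]) / semi[1])^2
  dy2 <- ((y - centre[2]) / semi[2])^2
  dz2 <- ((z - centre[3]) / semi[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) < 1
}

# Blocky spatial noise field: white noise on a coarse grid, upsampled by
# replication. Gives the dose/CT a controllable texture scale.
coarse_noise <- function(shape, block = 3L) {
  cs <- pmax(1L, ceiling(shape / block))
  g <- array(stats::rnorm(prod(cs)), cs)
  g[pmin(ceiling(seq_len(shape[1]) / block), cs[1]),
    pmin(ceiling(seq_len(shape[2]) / block), cs[2]),
    pmin(ceiling(seq_len(shape[3]) / block), cs[3]), drop = FALSE]
}

# Beam-like fractional dose field. Axis "ap" runs along y, "lat" along x;
# the profile is Gaussian in the two transverse directions and nearly flat
# along the beam, mimicking a broad treatment field through the target.
beam_field <- function(shape, target, width, axis = c("ap", "lat")) {
  axis <- match.arg(axis)
  x <- seq_len(shape[1]); y <- seq_len(shape[2]); z <- seq_len(shape[3])
  gz <- exp(-((z - target[3])^2) / (2 * (width * 1.4)^2))
  if (axis == "ap") {
    gx <- exp(-((x - target[1])^2) / (2 * width^2))
    gy <- 1 - 0.15 * abs(y - target[2]) / shape[2]   # mild depth falloff
  } else {
    gx <- 1 - 0.15 * abs(x - target[1]) / shape[1]
    gy <- exp(-((y - target[2])^2) / (2 * width^2))
  }
  outer(outer(gx, gy, `*`), gz, `*`)
}

#' Generate a synthetic phantom cohort
#'
#' See [cohort_spec()] for the anatomy, dose and outcome model. The
#' per-fraction dose grids alternate between an antero-posterior and a
#' lateral beam arrangement, so per-voxel doses genuinely differ across
#' fractions while the planned total is held at the prescription.
#'
#' @param spec a [cohort_spec()].
#' @return A list of `phantom_patient` objects, each with fields
#'   `patient_id`, `ct`, `fraction_doses`, `lung_mask`, `gtv_mask`
#'   (`NULL` for esophageal), `rp_grade`, `cancer_type`, and the latent
#'   generator covariates `mld`, `het_score`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  shape <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  n <- spec$n_patients
  lung_ct <- spec$cancer_type == "lung"
  rx_mean <- if (lung_ct) 59.4 else 50.4

  patients <- vector("list", n)
  mld <- numeric(n); het <- numeric(n)
  ct_dspec <- discretization_spec("ct")

  for (p in seq_len(n)) {
    # --- anatomy -----------------------------------------------------------
    cl <- c(0.30, 0.52, 0.50) * shape + stats::rnorm(3, 0, 0.4)
    cr <- c(0.70, 0.52, 0.50) * shape + stats::rnorm(3, 0, 0.4)
    semi <- c(0.15, 0.26, 0.36) * shape * stats::runif(1, 0.9, 1.1)
    lungs <- ellipsoid_mask(shape, cl, semi) | ellipsoid_mask(shape, cr, semi)
    gtv <- NULL
    if (lung_ct) {
      side <- if (stats::runif(1) < 0.5) cl else cr
      gcen <- side + stats::rnorm(3, 0, 1)
      gtv_vals <- ellipsoid_mask(shape, gcen, rep(max(2, 0.06 * min(shape)), 3))
      gtv <- roi_mask(gtv_vals, sp)
    }

    # --- latent heterogeneity driver --------------------------------------
    tau <- stats::runif(1, 0.05, 0.45)   # dose texture amplitude
    lesion_rate <- tau * 20              # CT lesion burden rides on the same latent

    # --- CT ----------------------------------------------------------------
    ct_vals <- array(40 + stats::rnorm(prod(shape), 0, 15), shape)
    ct_vals[lungs] <- -700 + stats::rnorm(sum(lungs), 0, 30)
    n_lesions <- stats::rpois(1, lesion_rate)
    if (n_lesions > 0) {
      lung_idx <- which(lungs, arr.ind = TRUE)
      for (q in seq_len(n_lesions)) {
        cen <- lung_idx[sample.int(nrow(lung_idx), 1), ]
        les <- ellipsoid_mask(shape, cen, rep(stats::runif(1, 1.2, 2.2), 3)) & lungs
        ct_vals[les] <- ct_vals[les] + stats::runif(1, 250, 500)
      }
    }
    ct_vals <- pmax(pmin(ct_vals, 1200), -1024)
    ct <- image_volume(ct_vals, sp, modality = "CT_HU")

    # --- dose --------------------------------------------------------------
    nf <- if (spec$n_fractions_range[1] == spec$n_fractions_range[2]) {
      spec$n_fractions_range[1]
    } else sample(spec$n_fractions_range[1]:spec$n_fractions_range[2], 1)
    rx <- stats::rnorm(1, rx_mean, 2.5)
    target <- if (lung_ct) {
      (cl + cr) / 2 + stats::rnorm(3, 0, 1) + c(stats::runif(1, -0.2, 0.2) * shape[1], 0, 0)
    } else c(0.5, 0.5, 0.5) * shape + stats::rnorm(3, 0, 1)
    width <- stats::runif(1, 0.10, 0.22) * mean(shape[1:2])
    mod <- 1 + tau * coarse_noise(shape, block = 3L)
    mod[mod < 0.1] <- 0.1
    ap <- beam_field(shape, target, width, "ap")
    lat <- beam_field(shape, target, width, "lat")
    per_fx <- rx / nf
    fractions <- vector("list", nf)
    for (i in seq_len(nf)) {
      base <- if (i %% 2 == 1) ap else lat
      jitter <- 1 + stats::rnorm(1, 0, 0.02)
      f <- per_fx * jitter * base * mod
      f[f < 0] <- 0
      fractions[[i]] <- image_volume(f, sp, modality = "DOSE_GY")
    }
    ds <- dose_series(fractions)

    lung_mask <- roi_mask(lungs, sp)
    total <- accumulate_eqd2(ds)
    mld[p] <- mean(total$values[lungs])
    lv <- discretize(ct, lung_mask, ct_dspec)$levels
    het[p] <- stats::var(as.numeric(lv[!is.na(lv)]))

    patients[[p]] <- structure(list(
      patient_id = sprintf("%s_%03d", substr(spec$cancer_type, 1, 4), p),
      ct = ct, fraction_doses = ds, lung_mask = lung_mask, gtv_mask = gtv,
      rp_grade = NA_integer_, cancer_type = spec$cancer_type,
      mld = mld[p], het_score = NA_real_
    ), class = "phantom_patient")
  }

  # --- outcome model -------------------------------------------------------
  hz <- if (stats::sd(het) > 0) (het - mean(het)) / stats::sd(het) else het * 0
  eps <- stats::rnorm(n, 0, spec$noise_sd)
  lp_no_int <- spec$effect_mld * mld + spec$effect_texture * hz + eps
  intercept <- calibrate_intercept(lp_no_int, spec$target_prevalence)
  prob <- stats::plogis(intercept + lp_no_int)
  positive <- stats::runif(n) < prob

  for (p in seq_len(n)) {
    patients[[p]]$het_score <- hz[p]
    patients[[p]]$rp_grade <- if (!positive[p]) 0L else if (lung_ct) {
      if (stats::runif(1) < 0.88) 2L else 3L
    } else {
      if (stats::runif(1) < 0.92) 1L else 2L
    }
  }
  patients
}

# Solve for the intercept giving the requested expected prevalence. The
# mean sigmoid is monotone in the intercept, so a root always exists; the
# error branch guards pathological linear predictors (infinite effects).
calibrate_intercept <- function(lp, target) {
  f <- function(a) mean(stats::plogis(a + lp)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) {
    stop(sprintf(
      "cannot calibrate prevalence %.3f: achievable range is [%.3f, %.3f]",
      target, mean(stats::plogis(lo + lp)), mean(stats::plogis(hi + lp))))
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Positive-outcome label of a phantom patient
#'
#' Esophageal patients are positive at RP grade >= 1, lung-cancer patients
#' at grade >= 2 (grade-1 events are not ascertained in the lung cohort).
#'
#' @param patients list of `phantom_patient` objects (or one).
#' @return Integer vector of 0/1 labels.
#' @export
rp_labels <- function(patients) {
  if (inherits(patients, "phantom_patient")) patients <- list(patients)
  vapply(patients, function(p) {
    thr <- if (p$cancer_type == "lung") 2L else 1L
    as.integer(p$rp_grade >= thr)
  }, integer(1))
}

#' Write / read a phantom cohort on disk
#'
#' Each CT, per-fraction dose and mask is written as a NIfTI file under
#' `directory`, with a CSV manifest listing patient id, cancer type, RP
#' grade and file paths (dose paths semicolon-joined). The round trip
#' through [read_cohort()] is lossless up to float32 NIfTI storage.
#'
#' @param patients list of `phantom_patient` objects.
#' @param directory output directory (created if needed).
#' @return Path of the manifest CSV.
#' @export
cohort_to_disk <- function(patients, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  rows <- lapply(patients, function(p) {
    base <- file.path(directory, p$patient_id)
    ct_path <- paste0(base, "_ct.nii.gz")
    write_volume(p$ct, ct_path)
    dose_paths <- vapply(seq_along(p$fraction_doses$fractions), function(i) {
      dp <- sprintf("%s_fx%02d.nii.gz", base, i)
      write_volume(p$fraction_doses$fractions[[i]], dp)
      dp
    }, character(1))
    lung_path <- paste0(base, "_lung.nii.gz")
    write_volume(p$lung_mask, lung_path)
    gtv_path <- ""
    if (!is.null(p$gtv_mask)) {
      gtv_path <- paste0(base, "_gtv.nii.gz")
      write_volume(p$gtv_mask, gtv_path)
    }
    data.frame(patient_id = p$patient_id, cancer_type = p$cancer_type,
               rp_grade = p$rp_grade, ct_path = ct_path,
               dose_paths = paste(dose_paths, collapse = ";"),
               lung_mask_path = lung_path, gtv_mask_path = gtv_path,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  mpath
}

#' @rdname cohort_to_disk
#' @param manifest_path path to a manifest CSV written by [cohort_to_disk()].
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(r) {
    row <- man[r, ]
    fr <- lapply(strsplit(row$dose_paths, ";")[[1]], read_volume, modality = "DOSE_GY")
    gtv <- NULL
    if (!is.na(row$gtv_mask_path) && nzchar(row$gtv_mask_path)) {
      gtv <- read_mask(row$gtv_mask_path)
    }
    structure(list(
      patient_id = row$patient_id,
      ct = read_volume(row$ct_path, "CT_HU"),
      fraction_doses = dose_series(fr),
      lung_mask = read_mask(row$lung_mask_path), gtv_mask = gtv,
      rp_grade = as.integer(row$rp_grade), cancer_type = row$cancer_type,
      mld = NA_real_, het_score = NA_real_
    ), class = "phantom_patient")
  })
}
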