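# The 78-feature catalog: 17 first-order + 24 GLCM + 16 GLRLM + 16 GLSZM +
# 5 NGTDM features per extraction context. First-order "mean" is deliberately
# absent: for dose it duplicates the MLD DVH feature, and the same 17-feature
# set is used in every context so all contexts share one catalog.

xlog2 <- function(p) ifelse(p > 0, log2(p), 0)

#' First-order intensity features (17)
#'
#' Computed on the raw intensities inside the ROI; `entropy` and
#' `uniformity` use the discretized level histogram. The set is the
#' standard first-order catalog minus the mean. Percentiles use the usual
#' linear-interpolation definition (R quantile type 7); dispersion moments
#' are population moments (denominator n). Skewness and kurtosis of a
#' constant region are defined as 0.
#'
#' @param x numeric vector of raw ROI intensities.
#' @param levels integer vector of discretized ROI levels (same voxels).
#' @return Named numeric vector of 17 features.
#' @export
first_order_features <- function(x, levels) {
  n <- length(x)
  if (n < 1L) stop("empty ROI")
  ph <- tabulate(levels) / n
  ph <- ph[ph > 0]
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  sub <- x[x >= q[1] & x <= q[5]]
  c(
    energy = sum(x^2),
    entropy = -sum(ph * log2(ph)),
    minimum = min(x),
    p10 = q[1],
    p90 = q[5],
    maximum = max(x),
    median = q[3],
    interquartile_range = q[4] - q[2],
    range = max(x) - min(x),
    mean_absolute_deviation = mean(abs(x - mu)),
    robust_mean_absolute_deviation = mean(abs(sub - mean(sub))),
    root_mean_squared = sqrt(mean(x^2)),
    standard_deviation = sqrt(m2),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    variance = m2,
    uniformity = sum(ph^2)
  )
}

#' GLCM features (24)
#'
#' Scalar features of a merged symmetric co-occurrence matrix. `Ng` in the
#' normalized inverse-difference features is the number of distinct levels
#' present. Degenerate (single-level) input: `correlation` and `mcc` are 1,
#' `imc1` is 0, `imc2` is 0.
#'
#' @param C count matrix from [glcm_matrix()].
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(C) {
  P <- C / sum(C)
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  present <- which(px > 0)
  ngp <- length(present)
  mux <- sum(px * seq_len(ng))
  sigx2 <- sum(px * (seq_len(ng) - mux)^2)
  # difference and sum distributions
  k_d <- 0:(ng - 1)
  pd <- vapply(k_d, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_s <- 2:(2 * ng)
  ps <- vapply(k_s, function(k) sum(P[(i + j) == k]), numeric(1))
  da <- sum(k_d * pd)
  hxy <- -sum(xlog2(P) * P)
  pxi <- px[i]; pyj <- px[j]
  hxy1 <- -sum(P * xlog2(pxi * pyj))
  hxy2 <- -sum(pxi * pyj * xlog2(pxi * pyj))
  hx <- -sum(px * xlog2(px))
  corr <- if (sigx2 > 0) (sum(P * i * j) - mux^2) / sigx2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  mcc <- if (ngp <= 1) 1 else {
    # Q[a,b] = sum_k P[a,k] P[b,k] / (px[a] px[k]), over present levels
    Pp <- P[present, present, drop = FALSE]
    pxp <- px[present]
    Q <- (Pp / pxp) %*% t(sweep(Pp, 2, pxp, "/"))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, ev[2]))
  }
  c(
    autocorrelation = sum(P * i * j),
    joint_average = mux,
    cluster_prominence = sum(P * (i + j - 2 * mux)^4),
    cluster_shade = sum(P * (i + j - 2 * mux)^3),
    cluster_tendency = sum(P * (i + j - 2 * mux)^2),
    contrast = sum(P * (i - j)^2),
    correlation = corr,
    difference_average = da,
    difference_entropy = -sum(pd * xlog2(pd)),
    difference_variance = sum(pd * (k_d - da)^2),
    inverse_difference = sum(P / (1 + abs(i - j))),
    inverse_difference_moment = sum(P / (1 + (i - j)^2)),
    idmn = sum(P / (1 + (i - j)^2 / ngp^2)),
    idn = sum(P / (1 + abs(i - j) / ngp)),
    imc1 = imc1,
    imc2 = imc2,
    inverse_variance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    joint_energy = sum(P^2),
    joint_entropy = hxy,
    mcc = mcc,
    maximum_probability = max(P),
    sum_average = sum(k_s * ps),
    sum_entropy = -sum(ps * xlog2(ps)),
    sum_squares = sigx2
  )
}

# shared machinery for the two level x size/length families
run_zone_features <- function(M, n_possible, elem_names) {
  Nr <- sum(M)
  p <- M / Nr
  iv <- row(M); lv <- col(M)
  pi_ <- rowSums(p); pl <- colSums(p)
  ii <- seq_len(nrow(M)); ll <- seq_len(ncol(M))
  mu_i <- sum(pi_ * ii); mu_l <- sum(pl * ll)
  out <- c(
    sum(p / (lv^2)),                       # short/small emphasis
    sum(p * lv^2),                         # long/large emphasis
    sum(rowSums(M)^2) / Nr,                # gray level non-uniformity
    sum(rowSums(M)^2) / Nr^2,              # ... normalized
    sum(colSums(M)^2) / Nr,                # run-length / size-zone NU
    sum(colSums(M)^2) / Nr^2,              # ... normalized
    Nr / n_possible,                       # run/zone percentage
    sum(p * (iv - mu_i)^2),                # gray level variance
    sum(p * (lv - mu_l)^2),                # run/zone variance
    -sum(p * xlog2(p)),                    # run/zone entropy
    sum(p / iv^2),                         # low gray level emphasis
    sum(p * iv^2),                         # high gray level emphasis
    sum(p / (iv^2 * lv^2)),                # short+low
    sum(p * iv^2 / lv^2),                  # short+high
    sum(p * lv^2 / iv^2),                  # long+low
    sum(p * iv^2 * lv^2)                   # long+high
  )
  names(out) <- elem_names
  out
}

#' GLRLM features (16)
#'
#' Run percentage uses the merged-matrix convention: the number of runs
#' divided by 13 times the number of ROI voxels (one run ceiling per
#' direction), so it always lies in (0, 1].
#'
#' @param R count matrix from [glrlm_matrix()].
#' @param n_voxels number of ROI voxels.
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(R, n_voxels) {
  run_zone_features(R, 13 * n_voxels, elem_names = c(
    "short_run_emphasis", "long_run_emphasis",
    "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
    "run_length_nonuniformity", "run_length_nonuniformity_normalized",
    "run_percentage", "gray_level_variance", "run_variance", "run_entropy",
    "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
    "short_run_low_gray_level_emphasis", "short_run_high_gray_level_emphasis",
    "long_run_low_gray_level_emphasis", "long_run_high_gray_level_emphasis"))
}

#' GLSZM features (16)
#'
#' @param Z count matrix from [glszm_matrix()].
#' @param n_voxels number of ROI voxels.
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(Z, n_voxels) {
  run_zone_features(Z, n_voxels, elem_names = c(
    "small_area_emphasis", "large_area_emphasis",
    "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
    "size_zone_nonuniformity", "size_zone_nonuniformity_normalized",
    "zone_percentage", "gray_level_variance", "zone_variance", "zone_entropy",
    "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
    "small_area_low_gray_level_emphasis", "small_area_high_gray_level_emphasis",
    "large_area_low_gray_level_emphasis", "large_area_high_gray_level_emphasis"))
}

#' NGTDM features (5)
#'
#' Degenerate inputs (all neighborhood differences zero, or a single
#' level present) return 0 for the affected features.
#'
#' @param m list from [ngtdm_matrix()].
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(m) {
  nv <- m$n_valid
  p <- m$n / nv
  s <- m$s
  act <- which(p > 0)
  ngp <- length(act)
  i <- act
  ps_sum <- sum(p * s)
  coarse <- if (ps_sum > 0) 1 / ps_sum else 0
  contrast <- if (ngp > 1) {
    sum(outer(p[act], p[act]) * outer(i, i, function(a, b) (a - b)^2)) /
      (ngp * (ngp - 1)) * sum(s) / nv
  } else 0
  ipi <- i * p[act]
  busy_den <- sum(abs(outer(ipi, ipi, "-")))
  busy <- if (busy_den > 0) ps_sum / busy_den else 0
  psi <- p[act] * s[act]
  cplx <- sum(abs(outer(i, i, "-")) *
                outer(psi, psi, "+") / outer(p[act], p[act], "+")) / nv
  strength <- if (sum(s) > 0) {
    sum(outer(p[act], p[act], "+") * outer(i, i, function(a, b) (a - b)^2)) / sum(s)
  } else 0
  c(coarseness = coarse, contrast = contrast, busyness = busy,
    complexity = cplx, strength = strength)
}

#' All 61 texture features of a level grid
#'
#' @param levels integer 3-D array of gray levels, `NA` outside the ROI.
#' @param n_levels matrix size; defaults to the highest level present.
#' @return Named numeric vector of 61 features, names prefixed
#'   `glcm__` / `glrlm__` / `glszm__` / `ngtdm__`.
#' @export
texture_features_from_levels <- function(levels, n_levels = max(levels, na.rm = TRUE)) {
  nv <- sum(!is.na(levels))
  g1 <- glcm_features(glcm_matrix(levels, n_levels))
  g2 <- glrlm_features(glrlm_matrix(levels, n_levels), nv)
  g3 <- glszm_features(glszm_matrix(levels, n_levels), nv)
  g4 <- ngtdm_features(ngtdm_matrix(levels, n_levels))
  out <- c(g1, g2, g3, g4)
  names(out) <- c(paste0("glcm__", names(g1)), paste0("glrlm__", names(g2)),
                  paste0("glszm__", names(g3)), paste0("ngtdm__", names(g4)))
  out
}

#' The full 78-feature first-order + texture catalog over one ROI
#'
#' Discretizes the volume inside the ROI and computes 17 first-order, 24
#' GLCM, 16 GLRLM, 16 GLSZM and 5 NGTDM features (78 total).
#'
#' @param v [image_volume()] (dose or CT).
#' @param roi [roi_mask()] with at least 2 voxels.
#' @param spec [discretization_spec()] matching the modality.
#' @return Named numeric vector of 78 features, prefixed by family
#'   (`firstorder__`, `glcm__`, ...).
#' @export
compute_features <- function(v, roi, spec) {
  nv <- sum(roi$values)
  if (nv < 2L) stop("texture extraction needs an ROI with at least 2 voxels, got ", nv)
  disc <- discretize(v, roi, spec)
  # crop to the ROI bounding box: matrices only see ROI voxels anyway
  lv <- crop_to_mask(disc$levels)
  fo <- first_order_features(v$values[roi$values], disc$levels[!is.na(disc$levels)])
  names(fo) <- paste0("firstorder__", names(fo))
  c(fo, texture_features_from_levels(lv, disc$n_levels))
}

crop_to_mask <- function(levels) {
  ok <- !is.na(levels)
  ix <- which(apply(ok, 1, any)); iy <- which(apply(ok, 2, any)); iz <- which(apply(ok, 3, any))
  levels[min(ix):max(ix), min(iy):max(iy), min(iz):max(iz), drop = FALSE]
}

#' Names of the 78-feature catalog
#' @return Character vector of 78 feature names in catalog order.
#' @export
feature_catalog <- function() {
  fo <- c("energy", "entropy", "minimum", "p10", "p90", "maximum", "median",
          "interquartile_range", "range", "mean_absolute_deviation",
          "robust_mean_absolute_deviation", "root_mean_squared",
          "standard_deviation", "skewness", "kurtosis", "variance", "uniformity")
  glcm <- c("autocorrelation", "joint_average", "cluster_prominence",
            "cluster_shade", "cluster_tendency", "contrast", "correlation",
            "difference_average", "difference_entropy", "difference_variance",
            "inverse_difference", "inverse_difference_moment", "idmn", "idn",
            "imc1", "imc2", "inverse_variance", "joint_energy", "joint_entropy",
            "mcc", "maximum_probability", "sum_average", "sum_entropy",
            "sum_squares")
  glrlm <- c("short_run_emphasis", "long_run_emphasis",
             "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
             "run_length_nonuniformity", "run_length_nonuniformity_normalized",
             "run_percentage", "gray_level_variance", "run_variance",
             "run_entropy", "low_gray_level_run_emphasis",
             "high_gray_level_run_emphasis", "short_run_low_gray_level_emphasis",
             "short_run_high_gray_level_emphasis",
             "long_run_low_gray_level_emphasis",
             "long_run_high_gray_level_emphasis")
  glszm <- c("small_area_emphasis", "large_area_emphasis",
             "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
             "size_zone_nonuniformity", "size_zone_nonuniformity_normalized",
             "zone_percentage", "gray_level_variance", "zone_variance",
             "zone_entropy", "low_gray_level_zone_emphasis",
             "high_gray_level_zone_emphasis",
             "small_area_low_gray_level_emphasis",
             "small_area_high_gray_level_emphasis",
             "large_area_low_gray_level_emphasis",
             "large_area_high_gray_level_emphasis")
  ngtdm <- c("coarseness", "contrast", "busyness", "complexity", "strength")
  c(paste0("firstorder__", fo), paste0("glcm__", glcm),
    paste0("glrlm__", glrlm), paste0("glszm__", glszm),
    paste0("ngtdm__", ngtdm))
}
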