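#' Resample a volume or mask onto a new isotropic/anisotropic grid
#'
#' Resamples a 3-D grid to a target voxel spacing. Scalar volumes use
#' smooth cubic-spline interpolation (`method = "bspline"`); masks and
#' label grids use nearest-neighbour (`method = "nearest"`), which can
#' never produce values outside the input set.
#'
#' Interpolation is separable: a 1-D interpolation operator is built per
#' axis and applied as a tensor contraction. The cubic interpolant passes
#' through every sample and reproduces constant and linear fields exactly
#' (natural end conditions), so a constant 50 Gy grid stays constant and a
#' linear dose ramp is preserved to machine precision.
#'
#' The target grid keeps the input origin (centre of the first voxel) and
#' covers the same physical extent to within one voxel; no extrapolation is
#' performed.
#'
#' @param v an [image_volume()] or [roi_mask()].
#' @param target_spacing_mm positive numeric triple (mm). A scalar is
#'   recycled to all three axes.
#' @param method `"bspline"` (smooth cubic interpolation, for scalar
#'   volumes) or `"nearest"` (for masks).
#' @return An object of the same class as `v` on the new grid.
#' @export
resample_volume <- function(v, target_spacing_mm,
                            method = c("bspline", "nearest")) {
  method <- match.arg(method)
  target_spacing_mm <- as.numeric(target_spacing_mm)
  if (length(target_spacing_mm) == 1L) target_spacing_mm <- rep(target_spacing_mm, 3)
  if (length(target_spacing_mm) != 3L || any(!is.finite(target_spacing_mm)) ||
      any(target_spacing_mm <= 0)) {
    stop("'target_spacing_mm' must be a positive numeric triple")
  }
  is_mask <- inherits(v, "roi_mask")
  if (is_mask && method != "nearest") {
    stop("masks must be resampled with method = 'nearest'")
  }
  vals <- if (is_mask) array(as.numeric(v$values), dim(v$values)) else v$values
  dims <- dim(vals)

  if (all(abs(target_spacing_mm - v$spacing_mm) < 1e-9)) {
    return(v)  # identity: same grid
  }

  out <- vals
  for (ax in 1:3) {
    n <- dim(out)[ax]
    op <- axis_resample_operator(n, v$spacing_mm[ax], target_spacing_mm[ax], method)
    out <- apply_axis_operator(out, op, ax)
  }

  if (is_mask) {
    roi_mask(out != 0, target_spacing_mm, v$origin_mm)
  } else {
    image_volume(out, target_spacing_mm, v$origin_mm, v$modality)
  }
}

# m x n linear operator mapping n samples at spacing sp onto targets at
# spacing sp_t, both grids anchored at the first sample centre. Targets are
# confined to the source support [0, (n-1)*sp].
axis_resample_operator <- function(n, sp, sp_t, method) {
  if (abs(sp - sp_t) < 1e-12) return(diag(n))
  m <- max(1L, floor((n - 1) * sp / sp_t + 1e-9) + 1L)
  xt <- (seq_len(m) - 1) * sp_t
  xs <- (seq_len(n) - 1) * sp
  if (method == "nearest") {
    idx <- pmin(pmax(round(xt / sp) + 1, 1), n)
    op <- matrix(0, m, n)
    op[cbind(seq_len(m), idx)] <- 1
    return(op)
  }
  if (n < 4) {
    # too few samples for a cubic: fall back to linear interpolation
    op <- matrix(0, m, n)
    if (n == 1L) { op[, 1] <- 1; return(op) }
    lo <- pmin(pmax(floor(xt / sp) + 1, 1), n - 1)
    t <- (xt - xs[lo]) / sp
    op[cbind(seq_len(m), lo)] <- 1 - t
    op[cbind(seq_len(m), lo + 1)] <- op[cbind(seq_len(m), lo + 1)] + t
    return(op)
  }
  # Interpolate each unit basis vector: columns of the operator. The cubic
  # spline with natural end conditions is linear in the data, so this
  # reconstructs the full operator exactly.
  op <- matrix(0, m, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    op[, j] <- stats::spline(xs, e, xout = xt, method = "natural")$y
  }
  op
}

# Contract a 3-D array with an m x n operator along axis `ax`.
apply_axis_operator <- function(a, op, ax) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  mat <- matrix(ap, nrow = d[ax])
  res <- op %*% mat
  newd <- c(nrow(op), d[perm[2]], d[perm[3]])
  res <- array(res, newd)
  aperm(res, order(perm))
}
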