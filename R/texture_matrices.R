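# Texture-matrix construction (GLCM, GLRLM, GLSZM, NGTDM) on a 3-D integer
# level grid with NA outside the ROI. Conventions: distance-1 neighborhoods,
# the 13 unique 3-D direction offsets (26-connectivity / 2), matrices merged
# (summed) over directions before feature computation.

#' The 13 unique distance-1 direction offsets in 3-D
#'
#' One representative per opposite pair of the 26 neighbors of a voxel.
#'
#' @return A 13 x 3 integer matrix of (dx, dy, dz) offsets.
#' @export
offsets_13 <- function() {
  m <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
  storage.mode(m) <- "integer"
  m
}

# Index ranges of the overlap between an array and its copy shifted by
# offset d along axis of length n: list(a = source idx, b = neighbor idx).
shift_ranges <- function(n, d) {
  if (d >= 0) list(a = seq_len(n - d), b = seq_len(n - d) + d)
  else list(a = seq_len(n + d) - d, b = seq_len(n + d))
}

check_levels_grid <- function(levels) {
  if (!is.array(levels) || length(dim(levels)) != 3L) {
    stop("'levels' must be a 3-D integer array with NA outside the ROI")
  }
  nv <- sum(!is.na(levels))
  if (nv < 2L) stop("texture matrices need at least 2 ROI voxels, got ", nv)
  invisible(nv)
}

#' Gray level co-occurrence matrix (GLCM)
#'
#' Symmetric co-occurrence counts at distance 1, summed over the 13 unique
#' 3-D directions; pairs are counted only when both voxels are inside the
#' ROI. Each unordered pair contributes to both (i,j) and (j,i), so the
#' total mass is twice the number of valid neighbor pairs.
#'
#' @param levels integer 3-D array of gray levels, `NA` outside the ROI.
#' @param n_levels matrix size; defaults to the highest level present.
#' @return `n_levels` x `n_levels` count matrix.
#' @export
glcm_matrix <- function(levels, n_levels = max(levels, na.rm = TRUE)) {
  check_levels_grid(levels)
  dims <- dim(levels)
  ng <- as.integer(n_levels)
  counts <- numeric(ng * ng)
  for (o in seq_len(nrow(offsets_13()))) {
    d <- offsets_13()[o, ]
    rx <- shift_ranges(dims[1], d[1]); ry <- shift_ranges(dims[2], d[2]); rz <- shift_ranges(dims[3], d[3])
    a <- levels[rx$a, ry$a, rz$a, drop = FALSE]
    b <- levels[rx$b, ry$b, rz$b, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    ai <- a[ok]; bi <- b[ok]
    counts <- counts + tabulate((ai - 1L) * ng + bi, nbins = ng * ng)
    counts <- counts + tabulate((bi - 1L) * ng + ai, nbins = ng * ng)
  }
  matrix(counts, ng, ng)
}

#' Gray level run length matrix (GLRLM)
#'
#' Run-length counts along each of the 13 directions, merged by summation.
#' A run is a maximal sequence of consecutive same-level ROI voxels along a
#' direction; out-of-ROI voxels break runs.
#'
#' @inheritParams glcm_matrix
#' @return `n_levels` x `max_run_length` count matrix.
#' @export
glrlm_matrix <- function(levels, n_levels = max(levels, na.rm = TRUE)) {
  check_levels_grid(levels)
  dims <- dim(levels)
  ng <- as.integer(n_levels)
  idx <- arrayInd(seq_along(levels), dims)
  lev <- as.integer(levels)
  runs_lev <- integer(0); runs_len <- integer(0)
  for (o in seq_len(nrow(offsets_13()))) {
    d <- offsets_13()[o, ]
    t <- idx[, 1] * d[1] + idx[, 2] * d[2] + idx[, 3] * d[3]
    # Line identifier: the cross product p x d is constant exactly along
    # lines of direction d, and t = p . d is strictly increasing along them.
    c1 <- idx[, 2] * d[3] - idx[, 3] * d[2]
    c2 <- idx[, 3] * d[1] - idx[, 1] * d[3]
    c3 <- idx[, 1] * d[2] - idx[, 2] * d[1]
    M <- 2L * max(dims) + 2L
    B <- as.numeric(2L * M + 2L)
    key <- (as.numeric(c1 + M) * B + (c2 + M)) * B + (c3 + M)
    ord <- order(key, t)
    kl <- key[ord]; ll <- lev[ord]
    n <- length(ll)
    same <- c(FALSE, kl[-1] == kl[-n] & !is.na(ll[-1]) & !is.na(ll[-n]) &
                ll[-1] == ll[-n])
    starts <- which(!same)
    lens <- diff(c(starts, n + 1L))
    keep <- !is.na(ll[starts])
    runs_lev <- c(runs_lev, ll[starts[keep]])
    runs_len <- c(runs_len, lens[keep])
  }
  maxlen <- max(runs_len)
  tab <- tabulate((runs_lev - 1L) * maxlen + runs_len, nbins = ng * maxlen)
  matrix(tab, ng, maxlen, byrow = TRUE)
}

#' Gray level size zone matrix (GLSZM)
#'
#' Zone-size counts: a zone is a 26-connected component of same-level ROI
#' voxels, independent of direction.
#'
#' @inheritParams glcm_matrix
#' @return `n_levels` x `max_zone_size` count matrix.
#' @export
glszm_matrix <- function(levels, n_levels = max(levels, na.rm = TRUE)) {
  check_levels_grid(levels)
  dims <- dim(levels)
  ng <- as.integer(n_levels)
  lin <- array(seq_along(levels), dims)
  mask_lin <- which(!is.na(levels))
  vid <- match(seq_along(levels), mask_lin)  # linear index -> vertex id
  efrom <- integer(0); eto <- integer(0)
  for (o in seq_len(nrow(offsets_13()))) {
    d <- offsets_13()[o, ]
    rx <- shift_ranges(dims[1], d[1]); ry <- shift_ranges(dims[2], d[2]); rz <- shift_ranges(dims[3], d[3])
    a <- levels[rx$a, ry$a, rz$a, drop = FALSE]
    b <- levels[rx$b, ry$b, rz$b, drop = FALSE]
    la <- lin[rx$a, ry$a, rz$a, drop = FALSE]
    lb <- lin[rx$b, ry$b, rz$b, drop = FALSE]
    ok <- !is.na(a) & !is.na(b) & a == b
    if (!any(ok)) next
    efrom <- c(efrom, vid[la[ok]])
    eto <- c(eto, vid[lb[ok]])
  }
  g <- igraph::make_graph(rbind(efrom, eto), n = length(mask_lin), directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  zone_level <- levels[mask_lin][match(seq_len(comp$no), comp$membership)]
  maxsz <- max(sizes)
  tab <- tabulate((zone_level - 1L) * maxsz + sizes, nbins = ng * maxsz)
  matrix(tab, ng, maxsz, byrow = TRUE)
}

#' Neighborhood gray tone difference matrix (NGTDM)
#'
#' For each ROI voxel with at least one ROI voxel among its 26 neighbors,
#' the absolute difference between its level and the mean level of those
#' neighbors is accumulated per level: `s_i` sums the differences, `n_i`
#' counts the voxels of level i.
#'
#' @inheritParams glcm_matrix
#' @return A list with vectors `s`, `n` (length `n_levels`) and `n_valid`,
#'   the number of voxels with a valid neighborhood.
#' @export
ngtdm_matrix <- function(levels, n_levels = max(levels, na.rm = TRUE)) {
  check_levels_grid(levels)
  dims <- dim(levels)
  ng <- as.integer(n_levels)
  nb_sum <- array(0, dims)
  nb_cnt <- array(0, dims)
  offs <- rbind(offsets_13(), -offsets_13())
  lev0 <- levels
  lev0[is.na(lev0)] <- 0L
  inroi <- !is.na(levels)
  for (o in seq_len(nrow(offs))) {
    d <- offs[o, ]
    rx <- shift_ranges(dims[1], d[1]); ry <- shift_ranges(dims[2], d[2]); rz <- shift_ranges(dims[3], d[3])
    nb_sum[rx$a, ry$a, rz$a] <- nb_sum[rx$a, ry$a, rz$a] + lev0[rx$b, ry$b, rz$b]
    nb_cnt[rx$a, ry$a, rz$a] <- nb_cnt[rx$a, ry$a, rz$a] + inroi[rx$b, ry$b, rz$b]
  }
  valid <- inroi & nb_cnt > 0
  diffs <- abs(levels[valid] - nb_sum[valid] / nb_cnt[valid])
  lv <- levels[valid]
  s <- vapply(seq_len(ng), function(i) sum(diffs[lv == i]), numeric(1))
  n <- tabulate(lv, nbins = ng)
  list(s = s, n = n, n_valid = sum(valid))
}
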