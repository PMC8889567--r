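#' SMOTE minority oversampling
#'
#' Balances a binary training set by synthesizing minority-class points:
#' each synthetic point is `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`
#' and `x_nn` one of the `k` nearest minority neighbours of `x`
#' (Euclidean distance; features are expected to be standardized before
#' calling). Synthetic points are therefore convex combinations of
#' minority pairs. Already balanced input is returned unchanged.
#'
#' @param features numeric matrix (rows = samples).
#' @param labels 0/1 vector; the rarer class is oversampled.
#' @param k number of nearest minority neighbours (reduced, with a
#'   warning, when the minority class has fewer than `k + 1` members).
#' @return List with the augmented `features`, `labels`, and `synthetic`,
#'   a logical flag per row.
#' @export
smote_balance <- function(features, labels, k = 5L) {
  features <- as.matrix(features)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (n1 == n0) {
    return(list(features = features, labels = labels,
                synthetic = rep(FALSE, length(labels))))
  }
  minority <- if (n1 < n0) 1 else 0
  need <- abs(n0 - n1)
  mi <- which(labels == minority)
  if (length(mi) < 2L) stop("SMOTE needs at least 2 minority samples")
  if (k > length(mi) - 1L) {
    warning("k reduced to ", length(mi) - 1L, " (minority size limit)", call. = FALSE)
    k <- length(mi) - 1L
  }
  X <- features[mi, , drop = FALSE]
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn_raw <- apply(D, 1, function(d) order(d)[seq_len(k)])
  nn <- if (k == 1L) matrix(nn_raw, ncol = 1) else t(nn_raw)
  base_idx <- rep_len(seq_along(mi), need)
  nb_idx <- nn[cbind(base_idx, sample.int(k, need, replace = TRUE))]
  u <- stats::runif(need)
  synth <- X[base_idx, , drop = FALSE] +
    u * (X[nb_idx, , drop = FALSE] - X[base_idx, , drop = FALSE])
  list(
    features = rbind(features, synth),
    labels = c(labels, rep(minority, need)),
    synthetic = c(rep(FALSE, length(labels)), rep(TRUE, need))
  )
}
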