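#' ROC and precision-recall AUC
#'
#' `roc_auc()` is the Mann-Whitney pairwise statistic: the probability that
#' a random positive scores above a random negative, ties counting 1/2.
#' `pr_auc()` integrates the precision-recall curve stepwise: scores are
#' swept from high to low (tied scores enter together) and each increment
#' of recall contributes `precision * delta_recall` at the precision of the
#' current cut — a step envelope, with no linear interpolation between
#' PR points.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels with both classes present.
#' @return A single AUC; `roc_pr_auc()` returns both as a named vector.
#' @export
roc_auc <- function(scores, labels) {
  check_binary(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname roc_auc
#' @export
pr_auc <- function(scores, labels) {
  check_binary(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores so a threshold never splits equal scores
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  n1 <- sum(y)
  recall <- tp / n1
  precision <- tp / (tp + fp)
  d_rec <- diff(c(0, recall))
  sum(precision * d_rec)
}

#' @rdname roc_auc
#' @export
roc_pr_auc <- function(scores, labels) {
  c(roc_auc = roc_auc(scores, labels), pr_auc = pr_auc(scores, labels))
}

check_binary <- function(labels) {
  u <- unique(labels)
  if (!all(u %in% c(0, 1))) stop("labels must be 0/1")
  if (length(u) < 2L) stop("both classes must be present to compute an AUC")
  invisible(TRUE)
}

#' Two-sample Z-test between per-split AUC distributions
#'
#' Compares the mean test-split AUCs of two models:
#' `z = (mean_a - mean_b) / sqrt(s_a^2/n + s_b^2/n)`, with a two-sided
#' normal p-value. The test treats the two AUC lists as independent
#' samples even when the models shared splits; `paired = TRUE` applies the
#' paired version (Z on the per-split differences), which is more powerful
#' when splits were reused.
#'
#' @param auc_a,auc_b numeric vectors of per-split AUCs, equal length.
#' @param paired use the paired Z on per-split differences.
#' @return List with `z`, `p_value`, `mean_a`, `mean_b`.
#' @export
compare_auc <- function(auc_a, auc_b, paired = FALSE) {
  n <- length(auc_a)
  if (n != length(auc_b)) stop("AUC lists must have equal length")
  if (n < 2L) stop("need at least 2 per-split results")
  if (paired) {
    d <- auc_a - auc_b
    se <- stats::sd(d) / sqrt(n)
    z <- if (se == 0) 0 else mean(d) / se
  } else {
    se <- sqrt(stats::var(auc_a) / n + stats::var(auc_b) / n)
    z <- if (se == 0) 0 else (mean(auc_a) - mean(auc_b)) / se
  }
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)),
       mean_a = mean(auc_a), mean_b = mean(auc_b))
}
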