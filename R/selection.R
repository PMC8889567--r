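#' Feature-selection configuration
#'
#' Two-stage univariate selection: (1) drop every feature whose univariate
#' logistic Wald p-value is >= `p_threshold` on the full cohort; (2) rank
#' the survivors by the mean held-out ROC AUC of an unregularized
#' univariate logistic model over `n_repeats` repetitions of stratified
#' `n_folds`-fold cross-validation, and keep the top `top_k` per feature
#' group.
#'
#' @param p_threshold univariate screening level (features with
#'   p >= threshold are eliminated); default 0.1.
#' @param n_folds folds per CV repetition; default 5.
#' @param n_repeats CV repetitions; default 50 (250 fold fits per feature).
#' @param top_k features kept per group; default 10.
#' @param seed RNG seed for the fold draws.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(p_threshold = 0.1, n_folds = 5L, n_repeats = 50L,
                             top_k = 10L, seed = 1L) {
  stopifnot(p_threshold > 0, p_threshold < 1, top_k >= 1, n_folds >= 2,
            n_repeats >= 1)
  structure(list(p_threshold = p_threshold, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), top_k = as.integer(top_k),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Univariate p-value screening
#'
#' Fits one single-covariate logistic regression (with intercept) per
#' feature and keeps those with Wald p strictly below the threshold.
#' Zero-variance features are excluded with a warning; perfectly
#' separating features get p = 0 and are kept.
#'
#' @param table feature table ([extract_cohort_features()]).
#' @param labels 0/1 outcome vector.
#' @param cfg a [selection_config()].
#' @param columns feature columns to screen; defaults to all feature
#'   columns in the table.
#' @return Data frame with `feature`, `p_value`, ordered by p, containing
#'   only survivors.
#' @export
univariate_filter <- function(table, labels, cfg = selection_config(),
                              columns = names(feature_groups(table))) {
  stopifnot(all(labels %in% c(0, 1)), length(unique(labels)) == 2)
  ps <- vapply(columns, function(cn) {
    x <- table[[cn]]
    if (anyNA(x)) return(NA_real_)
    univariate_logistic_p(x, labels)$p
  }, numeric(1))
  if (any(is.na(ps))) {
    warning(sum(is.na(ps)), " feature(s) skipped (constant or missing values)",
            call. = FALSE)
  }
  keep <- !is.na(ps) & ps < cfg$p_threshold
  out <- data.frame(feature = columns[keep], p_value = ps[keep],
                    stringsAsFactors = FALSE)
  out[order(out$p_value, out$feature), , drop = FALSE]
}

# Stratified fold assignment: shuffles within each class and deals folds
# round-robin, so every fold holds both classes at realistic prevalences.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Rank surviving features by repeated-CV univariate AUC
#'
#' For each survivor, an unregularized univariate logistic model is fit on
#' each training fold and scored by ROC AUC on the held-out fold, over
#' `n_repeats` independent stratified `n_folds`-fold partitions; the mean
#' of the fold AUCs is the feature's rank statistic. Ties are broken by
#' smaller screening p-value, then by name. Folds whose held-out part
#' lacks a class (possible when positives are fewer than `n_folds`) are
#' dropped from the mean.
#'
#' @inheritParams univariate_filter
#' @param survivors data frame from [univariate_filter()].
#' @return Data frame `feature`, `p_value`, `mean_cv_auc`, ordered by
#'   decreasing AUC.
#' @export
rank_by_repeated_cv <- function(table, labels, survivors,
                                cfg = selection_config()) {
  if (nrow(survivors) == 0L) stop("no surviving features to rank")
  set.seed(cfg$seed)
  n <- length(labels)
  feats <- survivors$feature
  X <- as.matrix(table[, feats, drop = FALSE])
  # standardize per feature: a univariate logistic fit is equivariant under
  # affine rescaling (identical fitted probabilities), and raw feature
  # scales (e.g. energy ~ 1e7) would otherwise ill-condition the Newton step
  X <- scale(X)
  aucs <- matrix(NA_real_, nrow = length(feats),
                 ncol = cfg$n_repeats * cfg$n_folds)
  col <- 0L
  for (r in seq_len(cfg$n_repeats)) {
    fold <- stratified_folds(labels, cfg$n_folds)
    for (f in seq_len(cfg$n_folds)) {
      col <- col + 1L
      tr <- fold != f; te <- !tr
      ytr <- labels[tr]; yte <- labels[te]
      # a held-out fold can lack a class when positives < n_folds; skip it
      if (length(unique(yte)) < 2 || length(unique(ytr)) < 2) next
      for (j in seq_along(feats)) {
        fit <- fit_l2_logistic(X[tr, j, drop = FALSE], ytr, lambda = 0)
        sc <- drop(X[te, j] * fit$coef) + fit$intercept
        aucs[j, col] <- roc_auc(sc, yte)
      }
    }
  }
  out <- data.frame(feature = feats, p_value = survivors$p_value,
                    mean_cv_auc = rowMeans(aucs, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  out[order(-out$mean_cv_auc, out$p_value, out$feature), , drop = FALSE]
}

#' Select the top features of each group
#'
#' Runs the two-stage procedure ([univariate_filter()] then
#' [rank_by_repeated_cv()]) separately within each feature group and keeps
#' the `top_k` of each. Groups with fewer survivors than `top_k` return
#' all survivors with a warning. Patients with missing feature values
#' (empty radiomic sub-ROIs) are dropped listwise per group.
#'
#' @inheritParams univariate_filter
#' @param groups which groups to select in.
#' @return List with one entry per group: a list holding `ranking` (the
#'   full ranked data frame) and `selected` (character vector of feature
#'   names).
#' @export
select_features <- function(table, labels, cfg = selection_config(),
                            groups = c("DVH", "dosiomic", "radiomic")) {
  out <- list()
  for (g in groups) {
    cols <- feature_columns(table, g)
    cc <- stats::complete.cases(table[, cols, drop = FALSE])
    if (!all(cc)) {
      message(sum(!cc), " patient(s) excluded from ", g,
              " selection (missing features)")
    }
    surv <- suppressWarnings(
      univariate_filter(table[cc, , drop = FALSE], labels[cc], cfg, cols)
    )
    if (nrow(surv) == 0L) {
      warning("no ", g, " features survive the p < ", cfg$p_threshold,
              " screen", call. = FALSE)
      out[[g]] <- list(ranking = surv, selected = character(0))
      next
    }
    rk <- rank_by_repeated_cv(table[cc, , drop = FALSE], labels[cc], surv, cfg)
    if (nrow(rk) < cfg$top_k) {
      warning(g, ": only ", nrow(rk), " survivors for top_k = ", cfg$top_k,
              call. = FALSE)
    }
    out[[g]] <- list(ranking = rk,
                     selected = utils::head(rk$feature, cfg$top_k))
  }
  out
}
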