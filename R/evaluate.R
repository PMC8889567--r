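#' Nested Monte-Carlo cross-validation configuration
#'
#' Outer loop: `n_outer_splits` random stratified train/test splits
#' (default 500 at 80/20). Inner loop, per outer split:
#' `n_inner_splits` Monte-Carlo splits of the outer training set (default
#' 250 at 80/20) choose the L2 strength from `reg_grid` that maximizes the
#' mean validation ROC AUC; SMOTE balances each inner training set (and
#' the final refit set). Standardization statistics come from training
#' data only.
#'
#' @param n_outer_splits outer Monte-Carlo splits.
#' @param outer_test_fraction held-out fraction per outer split.
#' @param n_inner_splits inner Monte-Carlo splits per outer split.
#' @param inner_val_fraction validation fraction per inner split.
#' @param reg_grid positive L2 strengths searched; default 13 log-spaced
#'   values spanning 1e-3 to 1e3.
#' @param smote_k SMOTE neighbour count.
#' @param seed RNG seed; fixes the whole split sequence, so models
#'   evaluated under the same config share identical splits.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(n_outer_splits = 500L, outer_test_fraction = 0.2,
                        n_inner_splits = 250L, inner_val_fraction = 0.2,
                        reg_grid = 10^seq(-3, 3, by = 0.5),
                        smote_k = 5L, seed = 1L) {
  stopifnot(outer_test_fraction > 0, outer_test_fraction < 1,
            inner_val_fraction > 0, inner_val_fraction < 1,
            length(reg_grid) >= 1, all(reg_grid > 0))
  structure(list(n_outer_splits = as.integer(n_outer_splits),
                 outer_test_fraction = outer_test_fraction,
                 n_inner_splits = as.integer(n_inner_splits),
                 inner_val_fraction = inner_val_fraction,
                 reg_grid = as.numeric(reg_grid),
                 smote_k = as.integer(smote_k), seed = as.integer(seed)),
            class = "eval_config")
}

# SMOTE when feasible; with fewer than 2 minority samples in a (tiny) inner
# training set the data are used as-is.
balance_or_pass <- function(x, y, k) {
  if (min(sum(y == 1), sum(y == 0)) < 2L) {
    return(list(features = x, labels = y))
  }
  suppressWarnings(smote_balance(x, y, k))
}

# Stratified random split: returns logical vector, TRUE = held out.
stratified_holdout <- function(labels, fraction) {
  test <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_te <- max(1L, round(length(idx) * fraction))
    test[sample(idx, n_te)] <- TRUE
  }
  test
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mean = mu, sd = sdv)
}
standardize_apply <- function(x, st) sweep(sweep(x, 2, st$mean), 2, st$sd, "/")

#' Evaluate one feature set with nested Monte-Carlo CV
#'
#' For each outer split: standardize on the outer-training rows, run the
#' inner Monte-Carlo grid search for the L2 strength (SMOTE-balancing each
#' inner training set), refit on the SMOTE-balanced outer-training set at
#' the chosen strength, and record test ROC AUC and PR AUC. Rows with
#' missing values in `features` are dropped listwise (with a message).
#'
#' @param table feature table.
#' @param labels 0/1 outcome vector aligned to `table`.
#' @param features character vector of feature columns to model.
#' @param cfg an [eval_config()].
#' @param model_name label stored in the result.
#' @return An `eval_summary` list: per-split `roc_auc` / `pr_auc` vectors
#'   plus `summary`, a data frame of mean, SD and 10th/90th percentiles of
#'   both metrics.
#' @export
evaluate_model <- function(table, labels, features, cfg = eval_config(),
                           model_name = "model") {
  missing_cols <- setdiff(features, colnames(table))
  if (length(missing_cols) > 0) {
    stop("feature columns absent from table: ",
         paste(missing_cols, collapse = ", "))
  }
  X_all <- as.matrix(table[, features, drop = FALSE])
  cc <- stats::complete.cases(X_all)
  if (!all(cc)) {
    message(sum(!cc), " patient(s) excluded from '", model_name,
            "' (missing features)")
  }
  X_all <- X_all[cc, , drop = FALSE]
  y_all <- labels[cc]
  if (min(sum(y_all == 1), sum(y_all == 0)) < 2L) {
    stop("each class needs at least 2 patients after exclusions")
  }

  set.seed(cfg$seed)
  split_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_outer_splits)
  roc <- numeric(cfg$n_outer_splits)
  pr <- numeric(cfg$n_outer_splits)
  lambda_star <- numeric(cfg$n_outer_splits)
  for (s in seq_len(cfg$n_outer_splits)) {
    set.seed(split_seeds[s])
    te <- stratified_holdout(y_all, cfg$outer_test_fraction)
    one <- evaluate_one_split(X_all, y_all, colnames(X_all), te, cfg)
    roc[s] <- one$roc; pr[s] <- one$pr; lambda_star[s] <- one$lambda
  }
  summarize_eval(model_name, roc, pr, lambda_star,
                 n_patients = length(y_all), features = features)
}

summarize_eval <- function(model_name, roc, pr, lambda_star, n_patients,
                           features) {
  qs <- function(x) stats::quantile(x, c(0.10, 0.90), names = FALSE, type = 7)
  structure(list(
    model = model_name, features = features, n_patients = n_patients,
    roc_auc = roc, pr_auc = pr, lambda_star = lambda_star,
    summary = data.frame(
      metric = c("roc_auc", "pr_auc"),
      mean = c(mean(roc), mean(pr)),
      sd = c(stats::sd(roc), stats::sd(pr)),
      p10 = c(qs(roc)[1], qs(pr)[1]),
      p90 = c(qs(roc)[2], qs(pr)[2])
    )
  ), class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("<eval_summary '%s'> %d splits, %d patients, %d features\n",
              x$model, length(x$roc_auc), x$n_patients, length(x$features)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: %.3f +/- %.3f (P10 %.3f, P90 %.3f)\n",
                s$metric[i], s$mean[i], s$sd[i], s$p10[i], s$p90[i]))
  }
  invisible(x)
}

#' Z-test comparison of two evaluated models
#'
#' @param summary_a,summary_b `eval_summary` objects from
#'   [evaluate_model()].
#' @param metric `"roc_auc"` or `"pr_auc"`.
#' @param paired use the paired Z variant (models share split sequences
#'   when run under the same `eval_config` seed).
#' @return List with `z`, `p_value`, `mean_a`, `mean_b` (see
#'   [compare_auc()]).
#' @export
compare_models <- function(summary_a, summary_b,
                           metric = c("roc_auc", "pr_auc"), paired = FALSE) {
  metric <- match.arg(metric)
  compare_auc(summary_a[[metric]], summary_b[[metric]], paired = paired)
}

#' Evaluate transferred features on a second cohort
#'
#' Trains and evaluates, on the target cohort, a model restricted to
#' features selected on a source cohort (e.g. dosiomic features selected
#' on esophageal patients, evaluated on lung-cancer patients). All
#' training happens on the target cohort; only the feature identity
#' transfers.
#'
#' @param selected character vector of source-selected feature names.
#' @param target_table feature table of the target cohort.
#' @param target_labels 0/1 outcome of the target cohort.
#' @param cfg an [eval_config()].
#' @param model_name label stored in the result.
#' @return An `eval_summary`.
#' @export
transfer_evaluate <- function(selected, target_table, target_labels,
                              cfg = eval_config(), model_name = "transfer") {
  evaluate_model(target_table, target_labels, selected, cfg, model_name)
}
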