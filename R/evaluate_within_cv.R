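#' Nested CV with feature selection inside each training split
#'
#' The default protocol selects features once on the full cohort, which
#' makes within-cohort test AUCs optimistic. This variant repeats the whole
#' two-stage selection ([select_features()]) on every outer training split
#' before tuning and refitting, so the held-out test patients never
#' influence feature choice — the leakage-free mode. It shares the split
#' machinery, SMOTE, solver and metrics with [evaluate_model()].
#'
#' Runtime scales with `n_outer_splits` times the cost of a full selection,
#' so reduced `selection_config(n_repeats = )` values are typical here.
#'
#' @param table feature table.
#' @param labels 0/1 outcome vector.
#' @param groups feature groups to select from; their top-k selections are
#'   concatenated into the model's feature set (e.g. `c("dosiomic",
#'   "radiomic")` for the combined model).
#' @param sel_cfg a [selection_config()] applied within each split.
#' @param cfg an [eval_config()].
#' @param model_name label stored in the result.
#' @return An `eval_summary`, as for [evaluate_model()].
#' @export
evaluate_model_within_cv <- function(table, labels, groups,
                                     sel_cfg = selection_config(n_repeats = 5),
                                     cfg = eval_config(),
                                     model_name = "within_cv") {
  all_cols <- unlist(lapply(groups, function(g) feature_columns(table, g)))
  X_meta <- table[, all_cols, drop = FALSE]
  cc <- stats::complete.cases(X_meta)
  if (!all(cc)) {
    message(sum(!cc), " patient(s) excluded from '", model_name,
            "' (missing features)")
  }
  tab <- table[cc, , drop = FALSE]
  y_all <- labels[cc]
  if (min(sum(y_all == 1), sum(y_all == 0)) < 2L) {
    stop("each class needs at least 2 patients after exclusions")
  }

  set.seed(cfg$seed)
  split_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_outer_splits)
  roc <- numeric(cfg$n_outer_splits)
  pr <- numeric(cfg$n_outer_splits)
  lambda_star <- numeric(cfg$n_outer_splits)
  feat_tally <- new.env(parent = emptyenv())
  for (s in seq_len(cfg$n_outer_splits)) {
    set.seed(split_seeds[s])
    te <- stratified_holdout(y_all, cfg$outer_test_fraction)
    sel_cfg_s <- sel_cfg
    sel_cfg_s$seed <- split_seeds[s] %% 1000000L
    sel <- suppressWarnings(suppressMessages(
      select_features(tab[!te, , drop = FALSE], y_all[!te], sel_cfg_s,
                      groups = groups)
    ))
    feats <- unlist(lapply(sel, `[[`, "selected"), use.names = FALSE)
    if (length(feats) == 0L) { roc[s] <- NA; pr[s] <- NA; next }
    for (f in feats) {
      assign(f, (if (exists(f, feat_tally)) get(f, feat_tally) else 0) + 1,
             feat_tally)
    }
    one <- evaluate_one_split(tab, y_all, feats, te, cfg)
    roc[s] <- one$roc; pr[s] <- one$pr; lambda_star[s] <- one$lambda
  }
  ok <- !is.na(roc)
  out <- summarize_eval(model_name, roc[ok], pr[ok], lambda_star[ok],
                        n_patients = length(y_all),
                        features = paste0("selected within CV: ",
                                          paste(groups, collapse = "+")))
  out$selection_counts <- sort(unlist(as.list(feat_tally)), decreasing = TRUE)
  out
}

# One outer split of the nested protocol: standardize on train, inner
# Monte-Carlo grid search with SMOTE, refit, score the held-out part.
evaluate_one_split <- function(tab, y_all, feats, te, cfg) {
  X_all <- as.matrix(tab[, feats, drop = FALSE])
  Xtr <- X_all[!te, , drop = FALSE]; ytr <- y_all[!te]
  Xte <- X_all[te, , drop = FALSE]; yte <- y_all[te]
  st <- standardize_fit(Xtr)
  Xtr <- standardize_apply(Xtr, st)
  Xte <- standardize_apply(Xte, st)
  grid_auc <- matrix(NA_real_, cfg$n_inner_splits, length(cfg$reg_grid))
  grid_order <- order(cfg$reg_grid, decreasing = TRUE)
  for (t in seq_len(cfg$n_inner_splits)) {
    val <- stratified_holdout(ytr, cfg$inner_val_fraction)
    if (length(unique(ytr[val])) < 2) next
    bal <- balance_or_pass(Xtr[!val, , drop = FALSE], ytr[!val], cfg$smote_k)
    warm <- NULL
    for (g in grid_order) {
      fit <- fit_l2_logistic(bal$features, bal$labels, cfg$reg_grid[g],
                             beta_init = warm)
      warm <- c(fit$intercept, fit$coef)
      grid_auc[t, g] <- roc_auc(
        predict_logistic(fit, Xtr[val, , drop = FALSE]), ytr[val])
    }
  }
  mean_auc <- colMeans(grid_auc, na.rm = TRUE)
  best <- max(which(mean_auc == max(mean_auc)))
  bal <- balance_or_pass(Xtr, ytr, cfg$smote_k)
  fit <- fit_l2_logistic(bal$features, bal$labels, cfg$reg_grid[best])
  sc <- predict_logistic(fit, Xte)
  list(roc = roc_auc(sc, yte), pr = pr_auc(sc, yte),
       lambda = cfg$reg_grid[best])
}
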