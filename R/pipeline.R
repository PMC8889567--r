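#' Full-study run configuration
#'
#' Bundles the sub-configurations of a complete two-cohort run: generate
#' phantom cohorts, accumulate doses, extract features, select features on
#' cohort A, evaluate the four models on cohort A, and transfer the
#' selections to cohort B (plus the DVH-selected-on-target baseline).
#' A single global seed fans out deterministically to every stage.
#'
#' @param cohort_a,cohort_b [cohort_spec()]s; defaults are an
#'   esophageal-like and a lung-like cohort.
#' @param extract an [extract_config()].
#' @param selection a [selection_config()].
#' @param evaluation an [eval_config()].
#' @param seed global seed, fanned out per stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort_a = NULL, cohort_b = NULL,
                       extract = extract_config(),
                       selection = selection_config(),
                       evaluation = eval_config(),
                       seed = 1L) {
  seed <- as.integer(seed)
  stage_seed <- function(k) (abs(seed) %% 1000000L) * 1000L + k
  if (is.null(cohort_a)) {
    cohort_a <- cohort_spec(101, "esophageal", seed = stage_seed(1L))
  }
  if (is.null(cohort_b)) {
    cohort_b <- cohort_spec(93, "lung", seed = stage_seed(2L))
  }
  selection$seed <- stage_seed(3L)
  evaluation$seed <- stage_seed(4L)
  structure(list(cohort_a = cohort_a, cohort_b = cohort_b,
                 extract = extract, selection = selection,
                 evaluation = evaluation, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Accepts a YAML file with optional blocks `cohort_a`, `cohort_b`,
#' `extract`, `selection`, `evaluation` and a top-level `seed`; each block
#' holds arguments of the corresponding constructor.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  mk <- function(block, ctor) {
    if (is.null(y[[block]])) NULL else do.call(ctor, y[[block]])
  }
  run_config(
    cohort_a = mk("cohort_a", cohort_spec),
    cohort_b = mk("cohort_b", cohort_spec),
    extract = mk("extract", extract_config) %||% extract_config(),
    selection = mk("selection", selection_config) %||% selection_config(),
    evaluation = mk("evaluation", eval_config) %||% eval_config(),
    seed = y$seed %||% 1L
  )
}

#' Run the whole study end to end
#'
#' Generates both phantom cohorts, extracts their feature tables, selects
#' the top features per group on cohort A, evaluates the DVH, dosiomic,
#' radiomic and dosiomic+radiomic models on cohort A, transfers the four
#' selections to cohort B together with the DVH-selected-on-B baseline,
#' and writes feature tables (CSV), selections (JSON), per-split metrics
#' (CSV), summaries (JSON), a pairwise Z-test table (CSV) and a
#' `MANIFEST.json` with the configuration into `output_dir`.
#'
#' @param config a [run_config()].
#' @param output_dir output directory (created if needed); `NULL` skips
#'   writing and returns results only.
#' @param verbose narrate stage progress.
#' @return (Invisibly) a list with `features_a`, `features_b`,
#'   `selection`, `eval_a`, `eval_b`, `comparisons_a`.
#' @export
run_full_study <- function(config, output_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  say("[1/6] generating cohorts (",
      config$cohort_a$n_patients, " + ", config$cohort_b$n_patients, " patients)")
  coh_a <- generate_cohort(config$cohort_a)
  coh_b <- generate_cohort(config$cohort_b)

  say("[2/6] extracting features, cohort A")
  ft_a <- extract_cohort_features(coh_a, config$extract, verbose = verbose)
  say("[2/6] extracting features, cohort B")
  ft_b <- extract_cohort_features(coh_b, config$extract, verbose = verbose)
  y_a <- ft_a$label; y_b <- ft_b$label

  say("[3/6] selecting features on cohort A")
  sel <- select_features(ft_a, y_a, config$selection)
  sets_a <- list(
    dvh = sel$DVH$selected,
    dosiomic = sel$dosiomic$selected,
    radiomic = sel$radiomic$selected,
    dosiomic_radiomic = c(sel$dosiomic$selected, sel$radiomic$selected)
  )

  say("[4/6] evaluating models on cohort A (",
      config$evaluation$n_outer_splits, " outer splits)")
  sets_a <- Filter(function(s) length(s) > 0, sets_a)
  eval_a <- lapply(names(sets_a), function(nm) {
    say("  model: ", nm)
    evaluate_model(ft_a, y_a, sets_a[[nm]], config$evaluation, nm)
  })
  names(eval_a) <- names(sets_a)

  say("[5/6] transfer to cohort B")
  sel_b_dvh <- select_features(ft_b, y_b, config$selection, groups = "DVH")
  sets_b <- c(sets_a, list(dvh_target = sel_b_dvh$DVH$selected))
  sets_b <- Filter(function(s) length(s) > 0, sets_b)
  eval_b <- lapply(names(sets_b), function(nm) {
    say("  model: ", nm)
    evaluate_model(ft_b, y_b, sets_b[[nm]], config$evaluation, paste0(nm, "_B"))
  })
  names(eval_b) <- names(sets_b)

  say("[6/6] pairwise model comparisons, cohort A")
  pairs <- utils::combn(names(eval_a), 2)
  comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    rows <- lapply(c("roc_auc", "pr_auc"), function(m) {
      cm <- compare_models(eval_a[[a]], eval_a[[b]], m)
      data.frame(model_a = a, model_b = b, metric = m, z = cm$z,
                 p_value = cm$p_value, mean_a = cm$mean_a, mean_b = cm$mean_b)
    })
    do.call(rbind, rows)
  }))

  res <- list(features_a = ft_a, features_b = ft_b, selection = sel,
              eval_a = eval_a, eval_b = eval_b, comparisons_a = comparisons)
  if (!is.null(output_dir)) write_study_outputs(res, config, output_dir)
  invisible(res)
}

write_study_outputs <- function(res, config, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$features_a, file.path(output_dir, "features_cohortA.csv"),
                   row.names = FALSE)
  utils::write.csv(res$features_b, file.path(output_dir, "features_cohortB.csv"),
                   row.names = FALSE)
  sel_out <- lapply(res$selection, function(s) {
    list(selected = s$selected, ranking = s$ranking)
  })
  jsonlite::write_json(sel_out, file.path(output_dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  per_split <- do.call(rbind, lapply(c(res$eval_a, res$eval_b), function(e) {
    data.frame(model = e$model, split = seq_along(e$roc_auc),
               roc_auc = e$roc_auc, pr_auc = e$pr_auc,
               lambda = e$lambda_star)
  }))
  utils::write.csv(per_split, file.path(output_dir, "metrics_per_split.csv"),
                   row.names = FALSE)
  summaries <- lapply(c(res$eval_a, res$eval_b), function(e) e$summary)
  jsonlite::write_json(summaries, file.path(output_dir, "summaries.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(res$comparisons_a, file.path(output_dir, "comparisons_cohortA.csv"),
                   row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dosiomicsRP")),
    r_version = R.version.string,
    seed = config$seed,
    n_cohort_a = config$cohort_a$n_patients,
    n_cohort_b = config$cohort_b$n_patients,
    n_outer_splits = config$evaluation$n_outer_splits,
    n_inner_splits = config$evaluation$n_inner_splits
  )
  jsonlite::write_json(manifest, file.path(output_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(output_dir)
}
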