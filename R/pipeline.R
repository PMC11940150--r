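#' Configuration of a full pipeline run
#'
#' Bundles the stage configurations: simulation, filtering,
#' segmentation, MIEE, cross-validation and bootstrap, plus the task
#' subset (`"all"` or `"tug"` to use TUG-derived features only).
#'
#' @param sim a [sim_config()].
#' @param fspec a [filter_spec()].
#' @param seg a [seg_params()].
#' @param miee a [miee_config()].
#' @param cv a [cv_config()].
#' @param task_subset `"all"` or `"tug"`.
#' @param n_boot bootstrap replicates for the report intervals.
#' @param importance_n_perm permutations per group for the importance
#'   analysis (0 skips it).
#' @param seed master seed; stage seeds default to offsets of it.
#' @param out_dir optional directory for artifacts (report JSON,
#'   feature table CSV, predictions CSV).
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(), fspec = filter_spec(),
                       seg = seg_params(), miee = miee_config(),
                       cv = cv_config(), task_subset = c("all", "tug"),
                       n_boot = 2000L, importance_n_perm = 20L,
                       seed = 1L, out_dir = NULL) {
  task_subset <- match.arg(task_subset)
  structure(list(sim = sim, fspec = fspec, seg = seg, miee = miee,
                 cv = cv, task_subset = task_subset,
                 n_boot = as.integer(n_boot),
                 importance_n_perm = as.integer(importance_n_perm),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline on a simulated (or supplied) cohort
#'
#' Simulate (or reuse) a cohort, low-pass filter every recording,
#' segment the complex tasks, assemble the feature table, cross-validate
#' the MIEE model, and evaluate: confusion matrix, metrics with BCa
#' intervals, selection tallies, and (on an internal stratified holdout)
#' grouped permutation importance of the five mobility tasks.
#'
#' @param config a [run_config()].
#' @param cohort optionally a pre-built `pdm_cohort` (skips simulation).
#' @param table optionally a pre-built `feature_table` (skips
#'   simulation + featurization).
#' @return List with `report` (an `evaluation_report`), `cv`
#'   (`cv_result`), `importance`, `table_dim`, and `config`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL,
                         table = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(table)) {
    if (is.null(cohort)) cohort <- simulate_cohort(config$sim)
    table <- assemble_feature_table(cohort, config$fspec, config$seg)
  }
  if (config$task_subset == "tug") table <- subset_task(table, "tug")
  labels <- table$labels
  cvres <- cross_validate(table, labels, config$cv, config$miee)
  report <- evaluate_cv(cvres, meta = table$meta,
                        n_replicates = config$n_boot,
                        seed = config$seed)
  importance <- NULL
  if (config$importance_n_perm > 0) {
    split <- with_seed(config$seed, stratified_folds(labels, 3L))
    train <- which(split != 1)
    test <- which(split == 1)
    prep <- preprocess_table(table, fit_rows = train)
    mcfg <- config$miee
    mcfg$seed <- config$seed + 101L
    model <- train_miee(prep$table, train, labels, mcfg)
    importance <- group_permutation_importance(
      model, prep$table, test, labels,
      n_perm = config$importance_n_perm, seed = config$seed + 202L)
  }
  out <- list(report = report, cv = cvres, importance = importance,
              table_dim = dim(table$values), config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(metrics = as.list(report$metrics),
           ci = report$ci,
           confusion = as.list(setNames(as.numeric(report$confusion),
                                        names(report$confusion))),
           importance = as.list(importance),
           task_fractions = as.list(report$tallies$task),
           n_features = ncol(table$values),
           seed = config$seed),
      file.path(config$out_dir, "report.json"), auto_unbox = TRUE,
      digits = NA)
    write.csv(cvres$final,
              file.path(config$out_dir, "predictions.csv"),
              row.names = FALSE)
  }
  out
}
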