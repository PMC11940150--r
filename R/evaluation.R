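#' Confusion matrix with an explicit positive class
#'
#' Rows are actual classes, columns predicted; the positive class (the
#' majority, PD, in this application) supplies TP/FN and the other
#' class TN/FP.
#'
#' @param truth,predicted label vectors, or counts via `counts`.
#' @param positive positive class level.
#' @param counts optionally, a named numeric vector
#'   `c(tp = , fn = , fp = , tn = )` instead of label vectors.
#' @return A `confusion_matrix` (named count vector with attributes).
#' @export
confusion_matrix <- function(truth = NULL, predicted = NULL,
                             positive = "pd", counts = NULL) {
  if (is.null(counts)) {
    pos <- truth == positive
    ppos <- predicted == positive
    counts <- c(tp = sum(pos & ppos), fn = sum(pos & !ppos),
                fp = sum(!pos & ppos), tn = sum(!pos & !ppos))
  }
  counts <- counts[c("tp", "fn", "fp", "tn")]
  if (any(counts < 0)) stop_pdm("negative counts", "pdm_eval_error")
  structure(as.numeric(counts),
            names = c("tp", "fn", "fp", "tn"),
            positive = positive, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(x[c("tp", "fn", "fp", "tn")], 2, 2, byrow = TRUE,
              dimnames = list(actual = c("pos", "neg"),
                              predicted = c("pos", "neg")))
  print(m)
  invisible(x)
}

# Rank-statistic (Mann-Whitney) AUC: scores oriented so that larger
# means more likely positive; ties handled by midranks.
auc_rank <- function(scores, truth, positive) {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics for imbalanced two-class problems
#'
#' Sensitivity = TP/(TP+FN) on the positive class, specificity =
#' TN/(TN+FP), balanced accuracy = their mean, F1 on the positive
#' class, and (when scores are given) AUC-ROC computed as the
#' normalised Mann-Whitney rank statistic.
#'
#' @param cm a [confusion_matrix()].
#' @param scores optional per-participant scores oriented toward the
#'   positive class.
#' @param truth labels matching `scores`.
#' @return Named numeric vector: `balanced_accuracy`, `sensitivity`,
#'   `specificity`, `f1`, and `auc` when scores are supplied.
#' @export
compute_metrics <- function(cm, scores = NULL, truth = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm[["tp"]]; fn <- cm[["fn"]]; fp <- cm[["fp"]]; tn <- cm[["tn"]]
  if (tp + fn == 0 || tn + fp == 0)
    stop_pdm("confusion matrix has an empty class", "pdm_eval_error")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (is.na(prec) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  out <- c(balanced_accuracy = (sens + spec) / 2, sensitivity = sens,
           specificity = spec, f1 = f1)
  if (!is.null(scores))
    out <- c(out, auc = auc_rank(scores, truth, attr(cm, "positive")))
  out
}

#' Balanced-bootstrap BCa confidence interval for a metric
#'
#' Resamples participants with replacement within each class at the
#' original class sizes (so every replicate preserves the cohort's
#' imbalance and class-conditional metrics stay defined) and forms the
#' bias-corrected accelerated interval. A degenerate bootstrap
#' distribution falls back to a flagged percentile (or zero-width)
#' interval.
#'
#' @param outcomes data frame of per-participant outcomes; must contain
#'   a `truth` column used as resampling strata.
#' @param metric_fun function of a resampled outcomes data frame
#'   returning a scalar.
#' @param n_replicates bootstrap replicates (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return List with `point`, `lower`, `upper`, `method`
#'   (`"bca"` or a flagged fallback).
#' @export
bca_bootstrap_ci <- function(outcomes, metric_fun, n_replicates = 10000L,
                             level = 0.95, seed = 1L) {
  stopifnot(is.data.frame(outcomes), "truth" %in% names(outcomes),
            n_replicates >= 100, level > 0, level < 1)
  point <- metric_fun(outcomes)
  bo <- with_seed(seed, boot::boot(
    outcomes,
    statistic = function(d, i) metric_fun(d[i, , drop = FALSE]),
    R = n_replicates, strata = as.factor(outcomes$truth)))
  t <- bo$t[is.finite(bo$t)]
  if (length(unique(t)) <= 1)
    return(list(point = point, lower = point, upper = point,
                method = "degenerate"))
  # at modest replicate counts BCa endpoints can clamp to the extreme
  # order statistics; that warning is expected and not actionable here
  ci <- tryCatch(
    withCallingHandlers(
      boot::boot.ci(bo, conf = level, type = "bca"),
      warning = function(w) {
        if (grepl("extreme order statistics", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (!is.null(ci) && !is.null(ci$bca))
    return(list(point = point, lower = ci$bca[1, 4],
                upper = ci$bca[1, 5], method = "bca"))
  alpha <- (1 - level) / 2
  q <- quantile(t, c(alpha, 1 - alpha), names = FALSE)
  list(point = point, lower = q[1], upper = q[2],
       method = "percentile_fallback")
}

#' Grouped permutation importance
#'
#' For each feature group (here, one mobility task), all member columns
#' are permuted simultaneously with the same row permutation, the model
#' is re-evaluated, and the mean decrease in balanced accuracy over
#' `n_perm` permutations is reported. Groups must cover every feature
#' the model uses; a group contributing no model feature scores 0.
#'
#' @param model a `miee_model`.
#' @param table a preprocessed `feature_table`.
#' @param rows evaluation row indices.
#' @param labels labels for all table rows.
#' @param group_map named character vector mapping feature name ->
#'   group (default: the table's task metadata).
#' @param n_perm permutations per group (default 50).
#' @param seed RNG seed.
#' @return Named numeric vector of mean balanced-accuracy decreases,
#'   sorted decreasing.
#' @export
group_permutation_importance <- function(model, table, rows, labels,
                                         group_map = NULL, n_perm = 50L,
                                         seed = 1L) {
  group_map <- group_map %||%
    setNames(table$meta$task, table$meta$name)
  used <- unique(unlist(lapply(model$members, `[[`, "features")))
  unmapped <- setdiff(used, names(group_map))
  if (length(unmapped) > 0)
    stop_pdm("model features missing from the group map", "pdm_eval_error")
  truth <- labels[rows]
  positive <- setdiff(model$levels, model$minority)[1]
  bacc <- function(pred) {
    cm <- confusion_matrix(truth, pred, positive = positive)
    unname(compute_metrics(cm)[["balanced_accuracy"]])
  }
  X <- table$values[rows, , drop = FALSE]
  base <- bacc(predict_probability(model, X)$label)
  groups <- unique(group_map)
  # one shared set of row permutations, so results do not depend on
  # group or feature order
  perms <- with_seed(seed, lapply(seq_len(n_perm), function(r)
    sample.int(nrow(X))))
  dec <- vapply(groups, function(g) {
    cols <- intersect(used, names(group_map)[group_map == g])
    if (length(cols) == 0) return(0)
    drops <- vapply(perms, function(perm) {
      Xp <- X
      Xp[, cols] <- X[perm, cols, drop = FALSE]
      base - bacc(predict_probability(model, Xp)$label)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  names(dec) <- groups
  sort(dec, decreasing = TRUE)
}

#' Tally of selected features by task, subtask and derivation
#'
#' Counts every feature selection event across repeats, folds and
#' balanced subsets of a cross-validation run and normalises to
#' fractions.
#'
#' @param cv_result a `cv_result`.
#' @param meta the column metadata of the feature table used.
#' @return List of named fraction vectors: `task`, `subtask` (within
#'   each task), `derivation`.
#' @export
selection_tally <- function(cv_result, meta) {
  sel <- cv_result$selections
  idx <- match(sel$feature, meta$name)
  if (anyNA(idx))
    stop_pdm("selected features missing from metadata", "pdm_eval_error")
  frac <- function(x) {
    t <- table(x)
    setNames(as.numeric(t) / length(x), names(t))
  }
  task <- meta$task[idx]
  list(task = sort(frac(task), decreasing = TRUE),
       subtask = lapply(split(meta$subtask[idx], task), frac),
       derivation = frac(meta$derivation[idx]))
}

#' Compare covariates of correctly and incorrectly classified
#' participants
#'
#' Within each true class, continuous covariates are compared between
#' correctly and incorrectly classified participants with a two-tailed
#' two-sample Student's t-test (pooled variance) and categorical
#' covariates with Pearson's chi-squared test (no continuity correction
#' unless requested). Groups with fewer than 2 members flag the test
#' as skipped.
#'
#' @param final_labels predicted labels.
#' @param truth true labels.
#' @param covariates data frame of participant covariates (numeric
#'   columns -> t-test, other columns -> chi-squared).
#' @param correct continuity correction for the chi-squared test.
#' @return Data frame: class, covariate, test, group means/sds,
#'   statistic, p_value, flag.
#' @export
misclassification_comparison <- function(final_labels, truth, covariates,
                                         correct = FALSE) {
  rows <- list()
  for (cl in unique(truth)) {
    in_cl <- truth == cl
    ok <- in_cl & (final_labels == truth)
    bad <- in_cl & (final_labels != truth)
    for (cov in names(covariates)) {
      x <- covariates[[cov]]
      if (is.numeric(x)) {
        if (sum(ok) < 2 || sum(bad) < 2) {
          rows[[length(rows) + 1]] <- data.frame(
            class = cl, covariate = cov, test = "t",
            mean_correct = mean(x[ok]), sd_correct = sd(x[ok]),
            mean_incorrect = mean(x[bad]), sd_incorrect = sd(x[bad]),
            statistic = NA_real_, p_value = NA_real_, flag = TRUE)
          next
        }
        tt <- t.test(x[ok], x[bad], var.equal = TRUE)
        rows[[length(rows) + 1]] <- data.frame(
          class = cl, covariate = cov, test = "t",
          mean_correct = mean(x[ok]), sd_correct = sd(x[ok]),
          mean_incorrect = mean(x[bad]), sd_incorrect = sd(x[bad]),
          statistic = unname(tt$statistic), p_value = tt$p.value,
          flag = FALSE)
      } else {
        tabd <- table(factor(ifelse(ok[in_cl], "correct", "incorrect")),
                      x[in_cl])
        res <- tryCatch(
          suppressWarnings(chisq.test(tabd, correct = correct)),
          error = function(e) NULL)
        rows[[length(rows) + 1]] <- data.frame(
          class = cl, covariate = cov, test = "chisq",
          mean_correct = NA_real_, sd_correct = NA_real_,
          mean_incorrect = NA_real_, sd_incorrect = NA_real_,
          statistic = if (is.null(res)) NA_real_ else
            unname(res$statistic),
          p_value = if (is.null(res)) NA_real_ else res$p.value,
          flag = is.null(res))
      }
    }
  }
  do.call(rbind, rows)
}

#' Nearest reference subtype by random-forest proximity
#'
#' Proximity between two rows is the fraction of trees in which they
#' land in the same terminal node, averaged over the ensemble members.
#' Each target row (for example a misclassified majority participant)
#' is assigned the reference subtype with the highest mean proximity.
#'
#' @param model a `miee_model` or a single `randomForest`.
#' @param table a preprocessed `feature_table` (or numeric matrix).
#' @param target_rows rows to assign.
#' @param ref_rows reference rows.
#' @param ref_subtypes subtype labels of `ref_rows`.
#' @return Data frame: row, nearest subtype, mean proximity.
#' @export
proximity_nearest_class <- function(model, table, target_rows, ref_rows,
                                    ref_subtypes) {
  if (length(ref_rows) == 0)
    stop_pdm("reference set is empty", "pdm_eval_error")
  X <- if (inherits(table, "feature_table")) table$values else
    as.matrix(table)
  idx <- c(target_rows, ref_rows)
  nt <- length(target_rows)
  members <- if (inherits(model, "miee_model")) model$members
             else list(list(features = colnames(X), forest = model))
  prox <- 0
  for (m in members) {
    pr <- predict(m$forest, X[idx, m$features, drop = FALSE],
                  proximity = TRUE)$proximity
    prox <- prox + pr / length(members)
  }
  cross <- prox[seq_len(nt), nt + seq_along(ref_rows), drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nt), function(i) {
    means <- tapply(cross[i, ], ref_subtypes, mean)
    data.frame(row = target_rows[i],
               subtype = names(means)[which.max(means)],
               proximity = max(means))
  }))
  out
}

#' Full evaluation report of a cross-validation run
#'
#' Confusion matrix (positive class = majority), the metric set with
#' BCa bootstrap confidence intervals, and the selection tallies.
#'
#' @param cv_result a `cv_result`.
#' @param meta feature-table column metadata (for tallies); optional.
#' @param n_replicates bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return An `evaluation_report` list.
#' @export
evaluate_cv <- function(cv_result, meta = NULL, n_replicates = 10000L,
                        seed = 1L) {
  truth <- cv_result$labels
  positive <- setdiff(unique(truth), cv_result$minority)[1]
  pred <- cv_result$final$label
  score <- 1 - cv_result$final$prob  # oriented toward the positive class
  cm <- confusion_matrix(truth, pred, positive = positive)
  metrics <- compute_metrics(cm, scores = score, truth = truth)
  outcomes <- data.frame(truth = truth, pred = pred, score = score)
  mk <- list(
    balanced_accuracy = function(d) unname(compute_metrics(
      confusion_matrix(d$truth, d$pred, positive))[["balanced_accuracy"]]),
    sensitivity = function(d) unname(compute_metrics(
      confusion_matrix(d$truth, d$pred, positive))[["sensitivity"]]),
    specificity = function(d) unname(compute_metrics(
      confusion_matrix(d$truth, d$pred, positive))[["specificity"]]),
    f1 = function(d) unname(compute_metrics(
      confusion_matrix(d$truth, d$pred, positive))[["f1"]]),
    auc = function(d) auc_rank(d$score, d$truth, positive))
  cis <- lapply(seq_along(mk), function(i)
    bca_bootstrap_ci(outcomes, mk[[i]], n_replicates = n_replicates,
                     seed = seed + i))
  names(cis) <- names(mk)
  structure(list(confusion = cm, metrics = metrics, ci = cis,
                 tallies = if (!is.null(meta))
                   selection_tally(cv_result, meta) else NULL,
                 positive = positive),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  for (nm in names(x$ci))
    cat(sprintf("  %-18s %.3f (%.3f, %.3f)\n", nm, x$ci[[nm]]$point,
                x$ci[[nm]]$lower, x$ci[[nm]]$upper))
  invisible(x)
}
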