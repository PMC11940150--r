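#' MIEE configuration
#'
#' Mutual-information-based feature selection for EasyEnsemble: the
#' training data are undersampled into `n_subsets` class-balanced
#' subsets, the `top_k` features by mutual information with the class
#' are selected per subset, one random forest of `n_trees` trees is
#' trained per subset, and predictions are averaged.
#'
#' @param n_subsets number of balanced subsets (default 5).
#' @param top_k features selected per subset (default 30).
#' @param n_trees trees per forest (default 1000).
#' @param seed RNG seed.
#' @return A `miee_config` list.
#' @export
miee_config <- function(n_subsets = 5L, top_k = 30L, n_trees = 1000L,
                        seed = 1L) {
  stopifnot(n_subsets >= 1, top_k >= 1, n_trees >= 1)
  structure(list(n_subsets = as.integer(n_subsets),
                 top_k = as.integer(top_k),
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "miee_config")
}

#' Cross-validation configuration
#'
#' Stratified k-fold cross-validation repeated with different seeds;
#' the final class per participant is the majority vote over repeats,
#' so the number of repeats must be odd.
#'
#' @param n_folds folds (default 3).
#' @param n_repeats repeats (odd; default 5).
#' @param seed base seed; per-repeat seeds are `seed + 0:(n_repeats-1)`
#'   unless `seeds` is given.
#' @param seeds optional explicit per-repeat seeds.
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_folds = 3L, n_repeats = 5L, seed = 1L,
                      seeds = NULL) {
  stopifnot(n_folds >= 2)
  if (n_repeats %% 2 == 0)
    stop_pdm("n_repeats must be odd so the majority vote is defined",
             "pdm_config_error")
  seeds <- seeds %||% (seed + seq_len(n_repeats) - 1L)
  stopifnot(length(seeds) == n_repeats)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 seeds = as.integer(seeds)), class = "cv_config")
}

#' Mutual information between each feature and the class
#'
#' Nearest-neighbour estimator (k = 3 by default) of the mutual
#' information, in nats, between each continuous feature column and a
#' discrete class label. A vanishing deterministic-free jitter
#' (1e-10 of the feature scale) breaks ties, so discrete-valued
#' features are handled too. Scores are non-negative; the ranking is
#' the selection order.
#'
#' @param X numeric matrix (rows = samples).
#' @param y class labels (2 or more classes present).
#' @param k neighbour count.
#' @return Named numeric vector of per-feature scores (nats).
#' @export
mutual_information_scores <- function(X, y, k = 3L) {
  X <- as.matrix(X)
  y <- as.factor(as.character(y))
  if (nlevels(y) < 2)
    stop_pdm("mutual information needs at least two classes present",
             "pdm_model_error")
  scale <- pmax(1, colMeans(abs(X), na.rm = TRUE))
  J <- X + matrix(rnorm(length(X)), nrow(X)) *
    rep(1e-10 * scale, each = nrow(X))
  mi <- cpp_mi_disc(J, as.integer(y), as.integer(k))
  names(mi) <- colnames(X)
  mi
}

#' Build class-balanced training subsets by majority undersampling
#'
#' Each subset contains every minority-class row plus an equal-size
#' uniform draw (without replacement) of majority rows; draws are
#' independent across subsets.
#'
#' @param labels training labels.
#' @param n_subsets number of subsets.
#' @param minority minority class level (default: the rarer label).
#' @return List of integer row-index vectors.
#' @export
build_balanced_subsets <- function(labels, n_subsets = 5L,
                                   minority = NULL) {
  tab <- table(labels)
  if (length(tab) < 2)
    stop_pdm("both classes must be present", "pdm_model_error")
  minority <- minority %||% names(tab)[which.min(tab)]
  if (tab[[minority]] > min(tab)) {
    warning("declared minority class is the larger one; swapping classes")
    minority <- names(tab)[which.min(tab)]
  }
  min_idx <- which(labels == minority)
  maj_idx <- which(labels != minority)
  lapply(seq_len(n_subsets), function(s)
    sort(c(min_idx, sample(maj_idx, length(min_idx)))))
}

#' Train a MIEE ensemble
#'
#' For each balanced subset, mutual information is computed on the
#' subset, the top `top_k` features are selected, and a random forest
#' is trained on the subset restricted to those features. The table is
#' expected to be preprocessed with a state fitted on the training rows
#' only.
#'
#' @param table a preprocessed `feature_table`.
#' @param rows training row indices.
#' @param labels labels for all table rows.
#' @param config a [miee_config()].
#' @param minority minority class level (default: rarer label among
#'   `rows`).
#' @return A `miee_model`: per-subset `(features, forest)` members plus
#'   the minority level and config.
#' @export
train_miee <- function(table, rows, labels, config = miee_config(),
                       minority = NULL) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values[rows, , drop = FALSE]
  y <- factor(as.character(labels[rows]))
  with_seed(config$seed, {
    tab <- table(y)
    minority <- minority %||% names(tab)[which.min(tab)]
    subsets <- build_balanced_subsets(y, config$n_subsets, minority)
    k <- config$top_k
    if (k > ncol(X)) {
      warning("top_k exceeds available features; using all")
      k <- ncol(X)
    }
    members <- lapply(subsets, function(idx) {
      mi <- mutual_information_scores(X[idx, , drop = FALSE], y[idx])
      feats <- names(sort(mi, decreasing = TRUE))[seq_len(k)]
      forest <- randomForest::randomForest(
        X[idx, feats, drop = FALSE], y[idx], ntree = config$n_trees)
      list(features = feats, forest = forest)
    })
    structure(list(members = members, minority = minority,
                   levels = levels(y), config = config),
              class = "miee_model")
  })
}

#' @export
print.miee_model <- function(x, ...) {
  cat(sprintf("<miee_model> %d members, %d features each, minority class '%s'\n",
              length(x$members), length(x$members[[1]]$features),
              x$minority))
  invisible(x)
}

#' Averaged ensemble probability of the minority class
#'
#' The arithmetic mean of the member forests' predicted minority-class
#' probabilities. The predicted label is the minority class when the
#' averaged probability is at least 0.5 (ties go to the minority
#' class).
#'
#' @param model a `miee_model`.
#' @param table a `feature_table` preprocessed with the model's state.
#' @param rows row indices to predict (default: all).
#' @return Data frame with `prob` (minority-class probability) and
#'   `label`.
#' @export
predict_probability <- function(model, table, rows = NULL) {
  X <- if (inherits(table, "feature_table")) table$values else
    as.matrix(table)
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  need <- unique(unlist(lapply(model$members, `[[`, "features")))
  miss <- setdiff(need, colnames(X))
  if (length(miss) > 0)
    stop_pdm("unknown feature columns at prediction time",
             "pdm_model_error")
  probs <- vapply(model$members, function(m)
    predict(m$forest, X[, m$features, drop = FALSE],
            type = "prob")[, model$minority], numeric(nrow(X)))
  if (nrow(X) == 1) probs <- matrix(probs, nrow = 1)
  p <- rowMeans(probs)
  other <- setdiff(model$levels, model$minority)[1]
  data.frame(prob = p,
             label = ifelse(p >= 0.5, model$minority, other))
}

# Stratified fold assignment with proportional allocation and
# randomised remainders; returns an integer fold id per row.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    nc <- length(idx)
    sizes <- rep(nc %/% n_folds, n_folds)
    extra <- nc %% n_folds
    if (extra > 0) {
      bump <- sample.int(n_folds, extra)
      sizes[bump] <- sizes[bump] + 1
    }
    fold[sample(idx)] <- rep(seq_len(n_folds), times = sizes)
  }
  fold
}

#' Repeated stratified cross-validation of the MIEE pipeline
#'
#' For each repeat, participants are assigned to stratified folds; per
#' fold, preprocessing, per-subset mutual-information selection and
#' forest training all use the training rows only, and probabilities
#' are recorded for the held-out rows, so every participant is tested
#' exactly once per repeat. The final class per participant is the
#' majority vote across repeats.
#'
#' @param table an unpreprocessed `feature_table`.
#' @param labels labels per row (default: `table$labels`).
#' @param cv a [cv_config()].
#' @param miee a [miee_config()].
#' @param minority minority class level (default: rarer label).
#' @return A `cv_result`: `predictions` (participant x repeat
#'   probabilities and labels), `final` (mean probability and
#'   majority-vote label per participant), `selections` (selected
#'   features per repeat/fold/subset), `minority`.
#' @export
cross_validate <- function(table, labels = NULL, cv = cv_config(),
                           miee = miee_config(), minority = NULL) {
  stopifnot(inherits(table, "feature_table"))
  labels <- labels %||% table$labels
  n <- nrow(table$values)
  tab <- table(labels)
  if (length(tab) < 2 || min(tab) < cv$n_folds)
    stop_pdm("each class needs at least n_folds members", "pdm_model_error")
  minority <- minority %||% names(tab)[which.min(tab)]
  preds <- list(); sels <- list()
  for (r in seq_len(cv$n_repeats)) {
    folds <- with_seed(cv$seeds[r], stratified_folds(labels, cv$n_folds))
    for (f in seq_len(cv$n_folds)) {
      test <- which(folds == f)
      train <- which(folds != f)
      prep <- preprocess_table(table, fit_rows = train)
      mcfg <- miee
      mcfg$seed <- as.integer((cv$seeds[r] + 7919L * f) %% .Machine$integer.max)
      model <- train_miee(prep$table, train, labels, mcfg, minority)
      pr <- predict_probability(model, prep$table, test)
      preds[[length(preds) + 1]] <- data.frame(
        participant = table$participants[test], row = test, repeat_ = r,
        fold = f, prob = pr$prob, label = pr$label)
      for (s in seq_along(model$members))
        sels[[length(sels) + 1]] <- data.frame(
          repeat_ = r, fold = f, subset = s,
          feature = model$members[[s]]$features)
    }
  }
  predictions <- do.call(rbind, preds)
  other <- setdiff(names(tab), minority)[1]
  final <- do.call(rbind, lapply(seq_len(n), function(i) {
    sub <- predictions[predictions$row == i, , drop = FALSE]
    votes <- sum(sub$label == minority)
    data.frame(participant = table$participants[i], row = i,
               prob = mean(sub$prob),
               label = if (votes > nrow(sub) / 2) minority else other,
               votes = votes)
  }))
  structure(list(predictions = predictions, final = final,
                 selections = do.call(rbind, sels), minority = minority,
                 labels = labels, cv = cv, miee = miee),
            class = "cv_result")
}

#' Classify held-out participants and score their percentile
#'
#' Held-out rows (for example participants excluded from training
#' because of an indeterminate diagnosis) are classified by a model
#' trained on the remaining participants; each prediction is reported
#' with the percentile of its score among all reference participants
#' assigned the same predicted class.
#'
#' @param model a `miee_model`.
#' @param table a `feature_table` preprocessed with the model's state.
#' @param rows held-out row indices.
#' @param reference data frame of reference predictions with columns
#'   `prob` and `label` (for example `cv_result$final`).
#' @return Data frame with `prob`, `label`, `percentile` and `flag`
#'   (`TRUE` when the reference class had fewer than 2 members).
#' @export
predict_held_out <- function(model, table, rows, reference) {
  pr <- predict_probability(model, table, rows)
  out <- pr
  out$percentile <- NA_real_
  out$flag <- FALSE
  for (i in seq_len(nrow(out))) {
    ref <- reference$prob[reference$label == out$label[i]]
    score <- if (out$label[i] == model$minority) out$prob[i]
             else 1 - out$prob[i]
    refs <- if (out$label[i] == model$minority) ref else 1 - ref
    if (length(refs) < 1) {
      out$flag[i] <- TRUE
      next
    }
    out$percentile[i] <- 100 * mean(refs <= score)
    if (length(refs) < 2) out$flag[i] <- TRUE
  }
  out
}
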