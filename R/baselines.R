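#' Unsupervised random-forest feature selection
#'
#' Features are ranked by the importance of a forest trained to
#' separate the real rows from a shadow copy in which every column is
#' independently permuted (so only marginal-destroying structure
#' counts, not the class label). A forward scan over the top 30 ranked
#' features then picks the prefix whose forest maximises out-of-bag
#' balanced accuracy on the training labels.
#'
#' @param X numeric training matrix.
#' @param y training labels.
#' @param n_trees forest size.
#' @param seed RNG seed.
#' @return List with `ranking` (all features, ranked) and `selected`
#'   (<= 30 features).
#' @export
unsupervised_rf_selection <- function(X, y, n_trees = 500L, seed = 1L) {
  with_seed(seed, {
    n <- nrow(X)
    shadow <- apply(X, 2, function(col) col[sample.int(n)])
    contrast <- rbind(X, shadow)
    lab <- factor(rep(c("real", "shadow"), each = n))
    rf <- randomForest::randomForest(contrast, lab, ntree = n_trees)
    imp <- randomForest::importance(rf)[, 1]
    ranking <- names(sort(imp, decreasing = TRUE))
    top <- head(ranking, 30)
    y <- factor(as.character(y))
    best <- -Inf; best_k <- 1
    for (k in seq_along(top)) {
      rfk <- randomForest::randomForest(X[, top[seq_len(k)], drop = FALSE],
                                        y, ntree = n_trees)
      bacc <- oob_balanced_accuracy(rfk, y)
      if (!is.na(bacc) && bacc > best) { best <- bacc; best_k <- k }
    }
    list(ranking = ranking, selected = top[seq_len(best_k)])
  })
}

oob_balanced_accuracy <- function(rf, y) {
  pred <- rf$predicted
  ok <- !is.na(pred)
  if (!any(ok)) return(NA_real_)
  mean(vapply(levels(y), function(l)
    mean(pred[ok & y == l] == l), numeric(1)), na.rm = TRUE)
}

#' Rank features by single-feature decision-tree F1
#'
#' Each feature is scored by the cross-validated F1 (positive class =
#' majority) of a depth-limited decision tree using that feature alone;
#' features are ranked by score.
#'
#' @param X numeric training matrix.
#' @param y binary training labels.
#' @param positive positive class for F1 (default: majority label).
#' @param n_folds internal folds.
#' @param maxdepth tree depth limit.
#' @param seed RNG seed.
#' @return Named numeric vector of F1 scores, sorted decreasing.
#' @export
f1_dt_ranking <- function(X, y, positive = NULL, n_folds = 3L,
                          maxdepth = 2L, seed = 1L) {
  y <- factor(as.character(y))
  positive <- positive %||% names(which.max(table(y)))
  with_seed(seed, {
    folds <- stratified_folds(y, n_folds)
    scores <- vapply(seq_len(ncol(X)), function(j) {
      pred <- character(length(y))
      for (f in seq_len(n_folds)) {
        tr <- folds != f; te <- folds == f
        d <- data.frame(x = X[tr, j], y = y[tr])
        fit <- rpart::rpart(y ~ x, d, method = "class",
                            control = rpart::rpart.control(
                              maxdepth = maxdepth, cp = 0, minsplit = 4))
        pred[te] <- as.character(predict(
          fit, data.frame(x = X[te, j]), type = "class"))
      }
      f1_score(y, pred, positive)
    }, numeric(1))
    names(scores) <- colnames(X)
    sort(scores, decreasing = TRUE)
  })
}

f1_score <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Supervised random-forest selection minimising AIC
#'
#' Features are ranked by supervised forest importance; a forward scan
#' over the ranking selects the prefix minimising
#' AIC = 2k - 2 log L, where the likelihood is the binomial likelihood
#' of the labels under the forest's out-of-bag predicted probabilities
#' and k is the number of features.
#'
#' @param X numeric training matrix.
#' @param y binary training labels.
#' @param max_k longest prefix scanned (default 30).
#' @param n_trees forest size.
#' @param seed RNG seed.
#' @return List with `ranking`, `selected`, `aic` (per prefix).
#' @export
supervised_rf_min_aic <- function(X, y, max_k = 30L, n_trees = 500L,
                                  seed = 1L) {
  y <- factor(as.character(y))
  with_seed(seed, {
    rf <- randomForest::randomForest(X, y, ntree = n_trees)
    imp <- randomForest::importance(rf)[, 1]
    ranking <- names(sort(imp, decreasing = TRUE))
    top <- head(ranking, max_k)
    aics <- vapply(seq_along(top), function(k) {
      rfk <- randomForest::randomForest(X[, top[seq_len(k)], drop = FALSE],
                                        y, ntree = n_trees)
      p <- rfk$votes[cbind(seq_along(y), match(y, colnames(rfk$votes)))]
      p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
      2 * k - 2 * sum(log(p))
    }, numeric(1))
    k <- which.min(aics)
    list(ranking = ranking, selected = top[seq_len(k)], aic = aics)
  })
}

# 3-nearest-neighbour label prediction from a Euclidean distance matrix.
knn_predict <- function(D, labels, idx, k) {
  vapply(idx, function(i) {
    nb <- order(D[i, -i])[seq_len(k)]
    others <- labels[-i][nb]
    names(which.max(table(others)))
  }, character(1))
}

#' Neighborhood Cleaning Rule undersampling of the majority class
#'
#' Majority rows misclassified by the 3-nearest-neighbour rule are
#' removed, and so are majority rows among the 3 neighbours of any
#' misclassified minority row.
#'
#' @param X numeric matrix.
#' @param y labels.
#' @param minority minority class level.
#' @param k neighbourhood size (default 3).
#' @return Integer vector of retained row indices.
#' @export
ncl_undersample <- function(X, y, minority = NULL, k = 3L) {
  y <- as.character(y)
  tab <- table(y)
  minority <- minority %||% names(tab)[which.min(tab)]
  D <- as.matrix(dist(X))
  n <- nrow(X)
  drop <- rep(FALSE, n)
  maj <- which(y != minority)
  pred_maj <- knn_predict(D, y, maj, k)
  drop[maj[pred_maj != y[maj]]] <- TRUE
  mins <- which(y == minority)
  pred_min <- knn_predict(D, y, mins, k)
  for (ii in seq_along(mins)) {
    if (pred_min[ii] == minority) next
    i <- mins[ii]
    nb <- setdiff(order(D[i, ]), i)[seq_len(k)]
    drop[nb[y[nb] != minority]] <- TRUE
  }
  which(!drop)
}

#' SMOTE oversampling of the minority class
#'
#' New minority rows are synthesised by convex interpolation between a
#' minority row and one of its k nearest minority neighbours, until the
#' classes are balanced.
#'
#' @param X numeric matrix.
#' @param y labels.
#' @param minority minority class level.
#' @param k neighbour count (default 5).
#' @return List with `X` and `y` including the synthetic rows.
#' @export
smote_oversample <- function(X, y, minority = NULL, k = 5L) {
  y <- as.character(y)
  tab <- table(y)
  minority <- minority %||% names(tab)[which.min(tab)]
  n_min <- sum(y == minority)
  n_need <- max(table(y)) - n_min
  if (n_need == 0) return(list(X = X, y = y))
  if (n_min < 2) {
    warning("SMOTE skipped: fewer than 2 minority rows")
    return(list(X = X, y = y))
  }
  Xm <- X[y == minority, , drop = FALSE]
  k <- min(k, n_min - 1)
  D <- as.matrix(dist(Xm))
  new <- matrix(NA_real_, n_need, ncol(X))
  for (r in seq_len(n_need)) {
    i <- sample.int(n_min, 1)
    nb <- setdiff(order(D[i, ]), i)[seq_len(k)]
    j <- nb[sample.int(k, 1)]
    lam <- runif(1)
    new[r, ] <- Xm[i, ] + lam * (Xm[j, ] - Xm[i, ])
  }
  colnames(new) <- colnames(X)
  list(X = rbind(X, new), y = c(y, rep(minority, n_need)))
}

#' Combined NCL + SMOTE resampling
#'
#' Applies the Neighborhood Cleaning Rule to the majority class and
#' then SMOTE to the minority class up to class parity.
#'
#' @inheritParams smote_oversample
#' @return List with `X`, `y`.
#' @export
resample_ncl_smote <- function(X, y, minority = NULL, seed = NULL) {
  run <- function() {
    keep <- ncl_undersample(X, y, minority)
    smote_oversample(X[keep, , drop = FALSE], y[keep], minority)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Run the baseline comparison suite
#'
#' Evaluates the alternative feature-selection models and the three
#' NCL+SMOTE sampling placements, plus plain random undersampling,
#' inside exactly the same repeated stratified cross-validation harness
#' (identical folds, preprocessing policy and metrics) used for the
#' MIEE model, so the comparison is controlled. Sampling never touches
#' held-out test rows.
#'
#' @param table a `feature_table` (typically restricted to TUG columns
#'   via [subset_task()]).
#' @param labels labels (default: `table$labels`).
#' @param cv a [cv_config()] (share it with the MIEE run to share folds).
#' @param methods subset of the available baseline names.
#' @param n_trees forest size for the baseline forests.
#' @return Data frame of metrics, one row per baseline.
#' @export
run_baseline_suite <- function(table, labels = NULL, cv = cv_config(),
                               methods = c("unsup_rf_fs_max_bacc",
                                           "mi_top30", "f1_dt_ranking",
                                           "sup_rf_min_aic",
                                           "ncl_smote_before_fs_orig",
                                           "ncl_smote_before_fs_sampled",
                                           "ncl_smote_after_fs_sampled",
                                           "random_undersample"),
                               n_trees = 500L) {
  stopifnot(inherits(table, "feature_table"))
  labels <- labels %||% table$labels
  tab <- table(labels)
  minority <- names(tab)[which.min(tab)]
  positive <- setdiff(names(tab), minority)[1]
  n <- nrow(table$values)
  results <- list()
  for (method in methods) {
    preds <- vector("list", cv$n_repeats)
    for (r in seq_len(cv$n_repeats)) {
      folds <- with_seed(cv$seeds[r], stratified_folds(labels, cv$n_folds))
      lab_r <- prob_r <- rep(NA_character_, n)
      prob_r <- rep(NA_real_, n)
      for (f in seq_len(cv$n_folds)) {
        te <- which(folds == f); tr <- which(folds != f)
        prep <- preprocess_table(table, fit_rows = tr)
        Xall <- prep$table$values
        fit <- baseline_fit(method, Xall[tr, , drop = FALSE], labels[tr],
                            minority, n_trees,
                            seed = cv$seeds[r] + 7919L * f)
        pm <- predict(fit$forest, Xall[te, fit$features, drop = FALSE],
                      type = "prob")
        prob_r[te] <- pm[, minority]
        lab_r[te] <- ifelse(pm[, minority] >= 0.5, minority, positive)
      }
      preds[[r]] <- list(label = lab_r, prob = prob_r)
    }
    votes <- rowSums(vapply(preds, function(p) p$label == minority,
                            logical(n)))
    final <- ifelse(votes > cv$n_repeats / 2, minority, positive)
    score <- 1 - rowMeans(vapply(preds, `[[`, numeric(n), "prob"))
    cm <- confusion_matrix(labels, final, positive = positive)
    met <- compute_metrics(cm, scores = score, truth = labels)
    results[[method]] <- data.frame(method = method, t(met))
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  out
}

# Fit one baseline on training data only; returns list(features, forest).
baseline_fit <- function(method, Xtr, ytr, minority, n_trees, seed) {
  y <- factor(as.character(ytr))
  train_rf <- function(X, yy, feats) {
    list(features = feats,
         forest = randomForest::randomForest(X[, feats, drop = FALSE],
                                             factor(as.character(yy)),
                                             ntree = n_trees))
  }
  with_seed(seed, switch(method,
    unsup_rf_fs_max_bacc = {
      sel <- unsupervised_rf_selection(Xtr, y, n_trees,
                                       seed = sample.int(1e6, 1))
      train_rf(Xtr, y, sel$selected)
    },
    mi_top30 = {
      mi <- mutual_information_scores(Xtr, y)
      feats <- names(sort(mi, decreasing = TRUE))[
        seq_len(min(30, length(mi)))]
      train_rf(Xtr, y, feats)
    },
    f1_dt_ranking = {
      sc <- f1_dt_ranking(Xtr, y, seed = sample.int(1e6, 1))
      train_rf(Xtr, y, names(sc)[seq_len(min(30, length(sc)))])
    },
    sup_rf_min_aic = {
      sel <- supervised_rf_min_aic(Xtr, y, n_trees = n_trees,
                                   seed = sample.int(1e6, 1))
      train_rf(Xtr, y, sel$selected)
    },
    ncl_smote_before_fs_orig = {
      rs <- resample_ncl_smote(Xtr, y, minority)
      sel <- supervised_rf_min_aic(rs$X, rs$y, n_trees = n_trees,
                                   seed = sample.int(1e6, 1))
      train_rf(Xtr, y, sel$selected)      # model on original data
    },
    ncl_smote_before_fs_sampled = {
      rs <- resample_ncl_smote(Xtr, y, minority)
      sel <- supervised_rf_min_aic(rs$X, rs$y, n_trees = n_trees,
                                   seed = sample.int(1e6, 1))
      train_rf(rs$X, rs$y, sel$selected)  # model on sampled data
    },
    ncl_smote_after_fs_sampled = {
      sel <- supervised_rf_min_aic(Xtr, y, n_trees = n_trees,
                                   seed = sample.int(1e6, 1))
      rs <- resample_ncl_smote(Xtr, y, minority)
      train_rf(rs$X, rs$y, sel$selected)  # FS on original, model sampled
    },
    random_undersample = {
      mins <- which(y == minority)
      maj <- sample(which(y != minority), length(mins))
      idx <- c(mins, maj)
      train_rf(Xtr[idx, , drop = FALSE], y[idx], colnames(Xtr))
    },
    stop_pdm(paste0("unknown baseline method: ", method),
             "pdm_config_error")))
}
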