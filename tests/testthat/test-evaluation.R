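test_that("metrics agree with direct count arithmetic", {
  cm <- confusion_matrix(counts = c(tp = 30, fn = 10, fp = 5, tn = 15))
  met <- compute_metrics(cm)
  expect_equal(met[["sensitivity"]], 30 / 40)
  expect_equal(met[["specificity"]], 15 / 20)
  expect_equal(met[["balanced_accuracy"]], (0.75 + 0.75) / 2)
  prec <- 30 / 35
  expect_equal(met[["f1"]], 2 * prec * 0.75 / (prec + 0.75))
  perfect <- compute_metrics(
    confusion_matrix(counts = c(tp = 10, fn = 0, fp = 0, tn = 5)))
  expect_true(all(perfect == 1))
  expect_error(compute_metrics(
    confusion_matrix(counts = c(tp = 0, fn = 0, fp = 1, tn = 1))),
    "empty class")
})

test_that("confusion matrices from labels count correctly", {
  truth <- c("pd", "pd", "pd", "nonpd", "nonpd")
  pred <- c("pd", "nonpd", "pd", "nonpd", "pd")
  cm <- confusion_matrix(truth, pred, positive = "pd")
  expect_equal(unname(cm[c("tp", "fn", "fp", "tn")]), c(2, 1, 1, 1))
  expect_error(confusion_matrix(counts = c(tp = -1, fn = 0, fp = 0,
                                           tn = 1)), "negative")
})

test_that("rank AUC equals the brute-force pair statistic and pROC", {
  set.seed(1)
  for (i in 1:5) {
    sc <- round(runif(40), 2)   # ties included
    tr <- sample(c("p", "n"), 40, replace = TRUE, prob = c(0.7, 0.3))
    p <- sc[tr == "p"]; n <- sc[tr == "n"]
    brute <- mean(outer(p, n, ">") + 0.5 * outer(p, n, "=="))
    expect_equal(pdmobility:::auc_rank(sc, tr, "p"), brute)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(
        tr, sc, levels = c("n", "p"), direction = "<", quiet = TRUE)))
      expect_equal(pdmobility:::auc_rank(sc, tr, "p"), ref)
    }
  }
})

test_that("BCa intervals are sane and degenerate cases flagged", {
  set.seed(2)
  d <- data.frame(truth = rep(c("a", "b"), each = 30),
                  x = c(rbinom(30, 1, 0.8), rbinom(30, 1, 0.4)))
  ci <- bca_bootstrap_ci(d, function(dd) mean(dd$x),
                         n_replicates = 500, seed = 3)
  expect_lte(ci$lower, ci$point)
  expect_gte(ci$upper, ci$point)
  expect_gte(ci$lower, 0)
  expect_lte(ci$upper, 1)
  const <- data.frame(truth = rep("a", 20), x = rep(1, 20))
  ci2 <- bca_bootstrap_ci(const, function(dd) mean(dd$x),
                          n_replicates = 200, seed = 4)
  expect_equal(c(ci2$lower, ci2$upper), c(1, 1))
  expect_equal(ci2$method, "degenerate")
})

test_that("95% BCa intervals cover a Bernoulli(0.7) mean at nominal-ish rate", {
  set.seed(5)
  hits <- vapply(1:200, function(i) {
    x <- rbinom(200, 1, 0.7)
    d <- data.frame(truth = rep("z", 200), x = x)
    ci <- bca_bootstrap_ci(d, function(dd) mean(dd$x),
                           n_replicates = 600, seed = 1000 + i)
    ci$lower <= 0.7 && 0.7 <= ci$upper
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("group permutation importance isolates the informative group", {
  tab <- mk_feature_table(60, 60, seed = 6, n_signal = 6, shift = 3)
  tab$meta$task <- rep(c("tug", "walk32ft", "stand_eo"), each = 20)
  model <- train_miee(tab, 1:60, tab$labels,
                      miee_config(n_trees = 50, top_k = 10, seed = 7))
  imp <- group_permutation_importance(model, tab, 1:60, tab$labels,
                                      n_perm = 10, seed = 8)
  expect_equal(names(imp)[1], "tug")
  # a group contributing no model feature scores exactly zero
  gm <- setNames(tab$meta$task, tab$meta$name)
  gm2 <- c(gm, empty_group = "imaging")
  names(gm2)[length(gm2)] <- "not_a_feature"
  imp2 <- group_permutation_importance(model, tab, 1:60, tab$labels,
                                       group_map = gm2, n_perm = 5,
                                       seed = 9)
  expect_equal(unname(imp2[["imaging"]]), 0)
  # importance is invariant to feature order within a group
  perm <- c(sample(1:60))
  tabp <- tab
  tabp$values <- tab$values[, perm]
  tabp$meta <- tab$meta[perm, ]
  imp3 <- group_permutation_importance(model, tabp, 1:60, tab$labels,
                                       n_perm = 10, seed = 8)
  expect_equal(imp3[names(imp)], imp)
  # unmapped model features raise an error
  gm3 <- gm[-(1:5)]
  expect_error(group_permutation_importance(
    model, tab, 1:60, tab$labels, group_map = gm3, n_perm = 2,
    seed = 1), "missing from the group map")
})

test_that("permuting every group together collapses accuracy to chance", {
  tab <- mk_feature_table(60, 30, seed = 10, n_signal = 6, shift = 3)
  model <- train_miee(tab, 1:60, tab$labels,
                      miee_config(n_trees = 50, top_k = 10, seed = 11))
  used <- unique(unlist(lapply(model$members, `[[`, "features")))
  truth <- tab$labels
  set.seed(12)
  baccs <- replicate(30, {
    Xp <- tab$values
    Xp[, used] <- Xp[sample.int(60), used]
    pred <- predict_probability(model, Xp)$label
    cm <- confusion_matrix(truth, pred, positive = "pd")
    compute_metrics(cm)[["balanced_accuracy"]]
  })
  expect_lt(abs(mean(baccs) - 0.5), 0.1)
})

test_that("selection tallies normalise to one and localise planted signal", {
  sel <- data.frame(repeat_ = 1, fold = 1, subset = 1,
                    feature = c("f1", "f2", "f3", "f1"))
  cvr <- list(selections = sel)
  meta <- data.frame(name = paste0("f", 1:3),
                     task = c("tug", "tug", "walk32ft"),
                     subtask = c("turn", "walk", "walk"),
                     derivation = "t1")
  tal <- selection_tally(cvr, meta)
  expect_equal(sum(tal$task), 1)
  expect_equal(unname(tal$task[["tug"]]), 0.75)
  one <- selection_tally(list(selections = sel[sel$feature != "f3", ]),
                         meta)
  expect_equal(unname(one$task[["tug"]]), 1)
})

test_that("misclassification tests match textbook formulas", {
  set.seed(13)
  x1 <- rnorm(50); x2 <- rnorm(50, 1)
  truth <- rep("pd", 100)
  final <- rep(c("pd", "nonpd"), each = 50)
  cov <- data.frame(score = c(x1, x2))
  res <- misclassification_comparison(final, truth, cov)
  sp <- sqrt(((50 - 1) * var(x1) + (50 - 1) * var(x2)) / 98)
  tstat <- (mean(x1) - mean(x2)) / (sp * sqrt(1 / 50 + 1 / 50))
  expect_equal(res$statistic[1], tstat, tolerance = 1e-9)
  # identical groups give t = 0
  same <- misclassification_comparison(
    rep(c("pd", "nonpd"), each = 20), rep("pd", 40),
    data.frame(v = rep(c(1, 2), 20)))
  expect_equal(same$statistic[1], 0)
  # 2x2 table (10,0;0,10) gives chi-squared 20 without correction
  fl <- rep(c("pd", "nonpd"), each = 10)
  tr <- rep("pd", 20)
  cv2 <- data.frame(g = factor(rep(c("m", "f"), each = 10)))
  res2 <- misclassification_comparison(fl, tr, cv2)
  expect_equal(res2$statistic[res2$test == "chisq"], 20)
  # tiny groups are flagged
  res3 <- misclassification_comparison(
    c("pd", "nonpd", rep("pd", 8)), rep("pd", 10),
    data.frame(v = rnorm(10)))
  expect_true(res3$flag[1])
})

test_that("proximity assigns duplicated rows to their own subtype", {
  set.seed(14)
  X <- rbind(matrix(rnorm(40 * 10), 40, 10),
             matrix(rnorm(40 * 10, 4), 40, 10))
  colnames(X) <- paste0("f", 1:10)
  y <- factor(rep(c("a", "b"), each = 40))
  rf <- randomForest::randomForest(X, y, ntree = 200)
  target <- X[c(1, 41), , drop = FALSE]
  Xq <- rbind(target, X[c(2:9, 42:49), ])
  res <- proximity_nearest_class(
    rf, Xq, 1:2, 3:18, rep(c("sub_a", "sub_b"), each = 8))
  expect_equal(res$subtype, c("sub_a", "sub_b"))
  expect_true(all(res$proximity >= 0 & res$proximity <= 1))
  expect_error(proximity_nearest_class(rf, Xq, 1:2, integer(0),
                                       character(0)), "empty")
})

test_that("proximity agrees with nearest centroid on separated clusters", {
  # majority cluster at the origin; two minority subtype clusters.
  # Targets are majority-labeled rows placed inside the subtype
  # clusters (the misclassification scenario): their nearest subtype
  # by forest proximity should match the generating cluster.
  set.seed(15)
  centers <- rbind(c1 = c(0, 0, 0), c2 = c(5, 0, 0), c3 = c(0, 5, 0))
  mk <- function(center, n) sweep(matrix(rnorm(n * 3, sd = 0.7), n, 3),
                                  2, center, "+")
  Xtrain <- rbind(mk(centers[1, ], 40), mk(centers[2, ], 15),
                  mk(centers[3, ], 15))
  colnames(Xtrain) <- paste0("f", 1:3)
  y <- factor(rep(c("pd", "nonpd"), c(40, 30)))
  rf <- randomForest::randomForest(Xtrain, y, ntree = 300)
  targets_X <- rbind(mk(centers[2, ], 10), mk(centers[3, ], 10))
  X <- rbind(targets_X, Xtrain)
  colnames(X) <- paste0("f", 1:3)
  refs <- 20 + 41:70       # the minority training rows
  res <- proximity_nearest_class(rf, X, 1:20, refs,
                                 rep(c("c2", "c3"), each = 15))
  cent_label <- vapply(1:20, function(i) {
    d <- apply(centers[2:3, ], 1, function(cc) sum((X[i, ] - cc)^2))
    c("c2", "c3")[which.min(d)]
  }, character(1))
  expect_gte(mean(res$subtype == cent_label), 0.8)
})
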