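test_that("mutual information matches the discrete oracle ln 2", {
  set.seed(1)
  y <- rep(c("a", "b"), each = 100)
  X <- cbind(dup = as.numeric(y == "a"), noise = rnorm(200))
  mi <- mutual_information_scores(X, y)
  expect_lt(abs(mi[["dup"]] - log(2)), 0.05)
  expect_error(mutual_information_scores(X, rep("a", 200)),
               "two classes")
})

test_that("independent features score near zero mutual information", {
  set.seed(2)
  y <- rep(c("a", "b"), each = 50)
  mis <- replicate(50,
    mutual_information_scores(cbind(x = rnorm(100)), y)[["x"]])
  expect_lt(mean(mis), 0.05)   # estimator bias band around 0
})

test_that("mutual information is invariant under monotone transforms", {
  set.seed(3)
  y <- rep(c("a", "b"), each = 100)
  x <- rnorm(200) + (y == "b") * 1.5
  m1 <- mutual_information_scores(cbind(v = x), y)[["v"]]
  m2 <- mutual_information_scores(cbind(v = exp(x)), y)[["v"]]
  m3 <- mutual_information_scores(cbind(v = x^3), y)[["v"]]
  expect_lt(abs(m1 - m2), 0.08)
  expect_lt(abs(m1 - m3), 0.08)
})

test_that("balanced subsets contain all minority plus matched majority", {
  set.seed(4)
  labels <- rep(c("pd", "nonpd"), c(173, 12))
  subs <- build_balanced_subsets(labels, 5)
  expect_length(subs, 5)
  for (s in subs) {
    expect_length(s, 24)
    expect_equal(sum(labels[s] == "nonpd"), 12)
    expect_equal(sum(labels[s] == "pd"), 12)
    expect_true(all(which(labels == "nonpd") %in% s))
  }
  expect_gt(length(unique(vapply(subs, paste, "", collapse = ","))), 1)
  # equal classes: subsets are full-class samples of equal size
  lab2 <- rep(c("pd", "nonpd"), each = 10)
  subs2 <- build_balanced_subsets(lab2, 2)
  expect_true(all(vapply(subs2, length, 1L) == 20))
  set.seed(9); a <- build_balanced_subsets(labels, 3)
  set.seed(9); b <- build_balanced_subsets(labels, 3)
  expect_identical(a, b)
})

test_that("training selects per-subset features deterministically", {
  tab <- mk_feature_table(40, 60, seed = 5, n_signal = 5)
  m1 <- train_miee(tab, 1:40, tab$labels,
                   miee_config(n_trees = 50, top_k = 10, seed = 6))
  m2 <- train_miee(tab, 1:40, tab$labels,
                   miee_config(n_trees = 50, top_k = 10, seed = 6))
  expect_length(m1$members, 5)
  expect_identical(lapply(m1$members, `[[`, "features"),
                   lapply(m2$members, `[[`, "features"))
  expect_warning(
    train_miee(tab, 1:40, tab$labels,
               miee_config(n_trees = 20, top_k = 500, seed = 6)),
    "top_k")
})

test_that("planted signal features are selected in most subsets", {
  tab <- mk_feature_table(60, 500, seed = 7, n_signal = 5, shift = 3)
  model <- train_miee(tab, 1:60, tab$labels,
                      miee_config(n_trees = 20, seed = 8))
  hits <- vapply(paste0("f", 1:5), function(f)
    sum(vapply(model$members, function(m) f %in% m$features, TRUE)),
    numeric(1))
  expect_gte(min(hits), 4)
})

test_that("ensemble probability is the member average with minority ties", {
  tab <- mk_feature_table(40, 30, seed = 9, n_signal = 3)
  model <- train_miee(tab, 1:40, tab$labels,
                      miee_config(n_trees = 30, seed = 10))
  pr <- predict_probability(model, tab)
  member_probs <- vapply(model$members, function(m)
    unname(predict(m$forest, tab$values[, m$features, drop = FALSE],
                   type = "prob")[, model$minority]),
    numeric(40))
  expect_equal(pr$prob, rowMeans(member_probs))
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  expect_true(all(pr$label[pr$prob >= 0.5] == model$minority))
  expect_equal(mean(c(0.2, 0.4, 0.6, 0.8, 1.0)), 0.6)
  bad <- tab
  colnames(bad$values) <- paste0("g", seq_len(ncol(bad$values)))
  expect_error(predict_probability(model, bad), "unknown feature")
})

test_that("cross-validation tests each participant once per repeat", {
  tab <- mk_feature_table(30, 40, seed = 11, n_signal = 4)
  cv <- cross_validate(tab, cv = cv_config(n_repeats = 3, seed = 12),
                       miee = miee_config(n_trees = 20, seed = 12))
  counts <- table(cv$predictions$row, cv$predictions$repeat_)
  expect_true(all(counts == 1))
  expect_equal(nrow(cv$predictions), 3 * 30)
  expect_equal(nrow(cv$final), 30)
  expect_false(anyNA(cv$final$label))
  # majority vote (PD, PD, nonPD, PD, nonPD) -> PD
  votes <- c("pd", "pd", "nonpd", "pd", "nonpd")
  expect_equal(names(which.max(table(votes))), "pd")
  expect_error(cv_config(n_repeats = 4), "odd")
  # 6 minority participants split over 3 folds -> 2 per fold
  lab6 <- rep(c("pd", "nonpd"), c(24, 6))
  f <- pdmobility:::with_seed(1, pdmobility:::stratified_folds(lab6, 3))
  expect_true(all(table(f[lab6 == "nonpd"]) == 2))
})

test_that("cross-validation is deterministic end-to-end", {
  tab <- mk_feature_table(30, 40, seed = 13, n_signal = 4)
  cv1 <- cross_validate(tab, cv = cv_config(n_repeats = 1, seed = 14),
                        miee = miee_config(n_trees = 20, seed = 14))
  cv2 <- cross_validate(tab, cv = cv_config(n_repeats = 1, seed = 14),
                        miee = miee_config(n_trees = 20, seed = 14))
  expect_identical(cv1$final, cv2$final)
  expect_identical(cv1$selections, cv2$selections)
})

test_that("removing test rows before fitting leaves the model bit-identical", {
  tab <- mk_feature_table(40, 50, seed = 15, n_signal = 3)
  train <- 1:30
  prep1 <- preprocess_table(tab, fit_rows = train)
  m1 <- train_miee(prep1$table, train, tab$labels,
                   miee_config(n_trees = 50, seed = 16))
  tab2 <- tab
  tab2$values <- tab$values[train, , drop = FALSE]
  tab2$labels <- tab$labels[train]
  tab2$participants <- tab$participants[train]
  prep2 <- preprocess_table(tab2, fit_rows = seq_along(train))
  m2 <- train_miee(prep2$table, seq_along(train), tab2$labels,
                   miee_config(n_trees = 50, seed = 16))
  expect_identical(prep1$state, prep2$state)
  expect_identical(lapply(m1$members, `[[`, "features"),
                   lapply(m2$members, `[[`, "features"))
  expect_identical(
    predict_probability(m1, prep1$table, train)$prob,
    predict_probability(m2, prep2$table, seq_along(train))$prob)
})

test_that("held-out predictions carry within-class percentiles", {
  tab <- mk_feature_table(40, 30, seed = 17, n_signal = 3)
  train <- 1:35
  prep <- preprocess_table(tab, fit_rows = train)
  model <- train_miee(prep$table, train, tab$labels,
                      miee_config(n_trees = 30, seed = 18))
  ref <- data.frame(prob = seq(0.1, 0.9, length.out = 9),
                    label = rep(c("pd", "nonpd"), c(5, 4)))
  ho <- predict_held_out(model, prep$table, 36:40, ref)
  expect_true(all(ho$percentile >= 0 & ho$percentile <= 100,
                  na.rm = TRUE))
  # the top-scoring member of its class sits at the 100th percentile
  ref2 <- data.frame(prob = c(0.9, 0.7), label = c("nonpd", "nonpd"))
  best <- predict_held_out(model, prep$table, which.max(
    predict_probability(model, prep$table)$prob), ref2)
  if (best$label == "nonpd" && best$prob >= 0.9)
    expect_equal(best$percentile, 100)
  # single-member reference class is flagged
  ref3 <- data.frame(prob = 0.99, label = "nonpd")
  ho3 <- predict_held_out(model, prep$table, 36, ref3)
  if (ho3$label == "nonpd") expect_true(ho3$flag)
})

test_that("an excluded duplicate of a training row scores like its twin", {
  tab <- mk_feature_table(41, 30, seed = 19, n_signal = 3)
  tab$values[41, ] <- tab$values[5, ]   # duplicate a minority row
  tab$labels[41] <- tab$labels[5]
  train <- 1:40
  prep <- preprocess_table(tab, fit_rows = train)
  model <- train_miee(prep$table, train, tab$labels,
                      miee_config(n_trees = 50, seed = 20))
  p_all <- predict_probability(model, prep$table)
  expect_gte(p_all$prob[41], p_all$prob[5] - 0.1)
})
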