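test_that("the registry has the fixed catalogue counts with unique names", {
  reg <- feature_registry()
  expect_length(reg$time, 42)
  expect_length(reg$frequency, 22)
  expect_length(reg$dft, 10)
  expect_length(reg$lsp, 10)
  expect_length(reg$pairwise, 3)
  for (dom in c("time", "frequency", "dft", "lsp", "pairwise"))
    expect_false(anyDuplicated(reg[[dom]]) > 0)
  expect_false(anyDuplicated(pdmobility:::window_feature_names()) > 0)
})

test_that("time-domain features match hand arithmetic", {
  tf <- time_domain_features(c(1, 2, 3, 4))
  expect_equal(tf[["mean"]], 2.5)
  expect_equal(tf[["variance"]], 5 / 3)   # unbiased
  expect_equal(tf[["rms"]], sqrt(30 / 4))
  expect_equal(tf[["median"]], 2.5)
  expect_equal(tf[["p25"]], unname(quantile(1:4, 0.25)))
  expect_equal(tf[["mad"]], mad(1:4))
  cst <- time_domain_features(rep(7, 20))
  expect_equal(cst[["mean"]], 7)
  expect_equal(cst[["sd"]], 0)
  expect_equal(cst[["rms"]], 7)
  expect_equal(cst[["range"]], 0)
  expect_length(tf, 42)
  expect_named(tf, feature_registry()$time)
  expect_error(time_domain_features(1), "at least 2")
})

test_that("time features agree with base-R formulas on random input", {
  set.seed(10)
  for (n in c(17, 200)) {
    x <- rnorm(n)
    tf <- time_domain_features(x)
    expect_equal(tf[["sd"]], sd(x))
    expect_equal(tf[["skewness"]],
                 mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5)
    expect_equal(tf[["kurtosis"]],
                 mean((x - mean(x))^4) / mean((x - mean(x))^2)^2)
    expect_equal(tf[["p95"]], unname(quantile(x, 0.95)))
    expect_equal(tf[["trimmed_mean10"]], mean(x, trim = 0.1))
    expect_equal(tf[["acf_lag2"]],
                 sum((x[1:(n - 2)] - mean(x)) * (x[3:n] - mean(x))) /
                   sum((x - mean(x))^2))
    expect_equal(tf[["diff_sd"]], sd(diff(x)))
  }
})

test_that("frequency features identify a pure tone", {
  fs <- 100
  t <- seq(0, 10 - 1 / fs, 1 / fs)
  ff <- frequency_domain_features(sin(2 * pi * 3 * t), fs)
  expect_length(ff, 22)
  expect_named(ff, feature_registry()$frequency)
  expect_lt(abs(ff[["dominant_freq"]] - 3), fs / length(t) + 1e-9)
  expect_gt(ff[["dominant_power_rel"]], 0.9)
  expect_error(frequency_domain_features(rnorm(5), fs), "at least 8")
})

test_that("white noise is spectrally flatter than any pure tone", {
  fs <- 100
  t <- seq(0, 5 - 1 / fs, 1 / fs)
  sine_flat <- max(vapply(c(1, 3, 7, 15), function(f)
    frequency_domain_features(sin(2 * pi * f * t), fs)[["flatness"]],
    numeric(1)))
  set.seed(20)
  noise_flat <- replicate(50,
    frequency_domain_features(rnorm(length(t)), fs)[["flatness"]])
  expect_true(all(noise_flat > sine_flat))
})

test_that("top power amplitudes behave like spectra", {
  fs <- 100
  t <- seq(0, 10 - 1 / fs, 1 / fs)
  x <- sin(2 * pi * 2 * t)
  for (m in c("dft", "lsp")) {
    a <- top_power_amplitudes(x, fs, m)
    expect_length(a, 10)
    expect_true(all(diff(a) <= 0))
    expect_gt(a[1] / a[2], 10)  # leakage bound for a 10 s unit tone
  }
  z <- top_power_amplitudes(rep(0, 100), fs, "dft")
  expect_true(all(z == 0))
  expect_true(all(top_power_amplitudes(rep(0, 100), fs, "lsp") == 0))
  expect_error(top_power_amplitudes(rnorm(15), fs, "dft"), "at least")
})

test_that("dft and lsp agree on the dominant peak of a sampled sine", {
  fs <- 100
  t <- seq(0, 8 - 1 / fs, 1 / fs)
  x <- sin(2 * pi * 4.3 * t) + rnorm(length(t), 0, 0.1)
  sp <- pdmobility:::onesided_psd(x, fs)
  f_dft <- sp$freq[which.max(sp$power)]
  lsp <- pdmobility:::cpp_lsp(x, t, pdmobility:::LSP_GRID)
  f_lsp <- pdmobility:::LSP_GRID[which.max(lsp)]
  expect_lt(abs(f_dft - f_lsp), 0.2)
})

test_that("pairwise features satisfy identity and sign symmetries", {
  set.seed(30)
  a <- rnorm(300)
  pf <- pairwise_features(a, a)
  expect_equal(pf[["corr"]], 1)
  expect_equal(pf[["max_xcorr"]], 1)
  expect_equal(pf[["mag_ratio"]], 1)
  expect_equal(pairwise_features(a, -a)[["corr"]], -1)
  cors <- replicate(50, pairwise_features(rnorm(200), rnorm(200))[["corr"]])
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(50))
  expect_error(pairwise_features(a, rnorm(10)), "equal-length")
})

test_that("documented scale behaviour holds under random rescaling", {
  set.seed(31)
  x <- rnorm(150)
  for (c in c(0.2, 5)) {
    tf1 <- time_domain_features(x)
    tf2 <- time_domain_features(c * x)
    expect_equal(tf2[["mean"]], c * tf1[["mean"]])
    expect_equal(tf2[["sd"]], c * tf1[["sd"]])
    expect_equal(tf2[["crest_factor"]], tf1[["crest_factor"]])
    expect_equal(pairwise_features(c * x, x)[["corr"]], 1)
  }
})

test_that("the assembled table has the deterministic schema", {
  coh <- simulate_cohort(sim_config(n_majority = 2, n_minority = 2,
                                    seed = 40))
  ft <- assemble_feature_table(coh)
  expect_equal(ncol(ft$values), 27999)
  # per segment per channel: 42 + 22 + 10 + 10 = 84; cross-channel 45
  one_seg <- ft$meta[ft$meta$task == "tug" & ft$meta$derivation == "t1" &
                     ft$meta$segpos == "turn1", ]
  expect_equal(sum(one_seg$channel == "acc_v"), 84)
  expect_equal(sum(one_seg$domain == "pairwise"), 45)
  expect_equal(nrow(one_seg), 6 * 84 + 45)
  expect_false(anyDuplicated(ft$meta$name) > 0)
  # identical runs give identical tables
  ft2 <- assemble_feature_table(simulate_cohort(
    sim_config(n_majority = 2, n_minority = 2, seed = 40)))
  expect_identical(ft$values, ft2$values)
})

test_that("trial derivations obey mean/diff algebra and missing trials", {
  coh <- simulate_cohort(sim_config(n_majority = 2, n_minority = 2,
                                    tasks = "tug", seed = 41))
  # make trial 2 a copy of trial 1 for participant 1
  coh$participants[[1]]$recordings$tug_2 <-
    coh$participants[[1]]$recordings$tug_1
  coh$participants[[1]]$recordings$tug_2$markers$trial <- 2L
  # drop trial 2 for participant 2
  coh$participants[[2]]$recordings$tug_2 <- NULL
  ft <- assemble_feature_table(coh)
  m <- ft$meta
  dcols <- m$task == "tug" & m$derivation == "diff"
  mcols <- m$task == "tug" & m$derivation == "mean"
  t1cols <- m$task == "tug" & m$derivation == "t1"
  expect_true(all(ft$values[1, dcols] == 0, na.rm = TRUE))
  expect_equal(unname(ft$values[1, mcols]), unname(ft$values[1, t1cols]))
  # participant 2: t1 present, t2/mean/diff missing, others untouched
  expect_false(anyNA(ft$values[2, t1cols]))
  expect_true(all(is.na(ft$values[2, m$derivation == "t2"])))
  expect_true(all(is.na(ft$values[2, dcols])))
  expect_equal(nrow(ft$values), 4)
})

test_that("preprocessing drops degenerate columns and imputes medians", {
  tab <- mk_feature_table(10, 6, seed = 50)
  tab$values[, 1] <- 7                        # constant
  tab$values[3, 2] <- Inf                     # non-finite
  tab$values[, 3] <- c(1, NA, 3, rep(2, 7))   # missing
  pr <- preprocess_table(tab, fit_rows = 1:3)
  expect_false("f1" %in% colnames(pr$table$values))
  expect_false("f2" %in% colnames(pr$table$values))
  expect_equal(unname(pr$table$values[2, "f3"]), 2)   # median of {1, 3}
  # the fitted state never uses held-out values
  tab2 <- tab
  tab2$values[4:10, 3] <- NA
  out <- apply_preprocess(pr$state, tab2)
  expect_true(all(out$values[4:10, "f3"] == 2))
  tab$values[1:3, ] <- 1
  expect_error(preprocess_table(tab, fit_rows = 1:3), "every column")
})
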