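test_that("confusion metrics reproduce the printed worked examples", {
  m <- confusion_metrics(list(TP = 37, FP = 3, TN = 67, FN = 9))
  expect_equal(m$accuracy, 104 / 116)
  expect_equal(round(m$accuracy, 2), 0.90)
  expect_equal(round(m$TPR, 2), 0.80)
  expect_equal(round(m$FPR, 2), 0.04)

  m2 <- confusion_metrics(list(TP = 42, FP = 5, TN = 65, FN = 4))
  expect_equal(round(m2$accuracy, 2), 0.92)
  expect_equal(round(m2$TPR, 2), 0.91)
  expect_equal(round(m2$FPR, 2), 0.07)
  expect_equal(confusion_metrics(list(TP = 42, FP = 5, TN = 65, FN = 4))$F1,
               84 / 93)

  perfect <- confusion_metrics(list(TP = 10, FP = 0, TN = 12, FN = 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$F1, 1)

  und <- confusion_metrics(list(TP = 0, FP = 0, TN = 5, FN = 0))
  expect_true(is.na(und$precision))  # undefined, not zero
  expect_true(is.na(und$TPR))
  expect_error(confusion_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "zero")
})

test_that("accuracy equals the mean per-gene correctness indicator", {
  set.seed(41)
  for (i in 1:10) {
    truth <- runif(30) > 0.5
    pred <- runif(30) > 0.5
    cc <- confusion_counts(pred, truth)
    expect_identical(cc$TP + cc$FN, sum(truth))
    expect_identical(cc$TN + cc$FP, sum(!truth))
    expect_equal(confusion_metrics(cc)$accuracy, mean(pred == truth))
  }
})

test_that("LOOCV runs n folds and solves wide-margin data perfectly", {
  sep <- make_separable(n_per_class = 10, d = 3, gap = 6, seed = 42)
  res <- loocv_svm(sep$X, sep$y, kernel_spec("linear"))
  expect_equal(res$n_folds, 20)
  expect_length(res$scores, 20)
  expect_equal(res$metrics$accuracy, 1)
  cc <- res$confusion
  expect_equal(cc$TP + cc$FN, 10)
  expect_equal(cc$TN + cc$FP, 10)
  expect_error(loocv_svm(sep$X[1:3, ], sep$y[1:3], kernel_spec("linear")),
               "at least 4")
})

test_that("nested and flat selection agree on easy data, ties break small", {
  sim <- quick_sim(seed = 43, n_pos = 8, n_neg = 10, effect_size = 4)
  fm <- sim_training_fm(sim, "micro")
  y <- sim_labels(sim)
  grid <- sigma_grid(n_points = 4)
  flat <- loocv_svm(fm, y, kernel_spec("rbf"), selection = "flat",
                    grid = grid)
  nested <- loocv_svm(fm, y, kernel_spec("rbf"), selection = "nested",
                      grid = grid)
  expect_equal(flat$metrics$accuracy, 1)
  expect_equal(nested$metrics$accuracy, 1)
  expect_true(flat$sigma %in% grid)
  expect_true(all(nested$sigma %in% grid))
  expect_length(nested$sigma, length(y))
  # explicit sigma: protocol "none"
  fixed <- loocv_svm(fm, y, kernel_spec("rbf", sigma = flat$sigma),
                     selection = "none")
  expect_equal(fixed$metrics$accuracy, 1)
})

test_that("LOOCV accuracy sits near the majority fraction under the null", {
  accs <- vapply(1:8, function(s) {
    sim <- quick_sim(seed = 400 + s, n_pos = 10, n_neg = 14,
                     effect_size = 0, p_peak_pos = 0.5, p_peak_neg = 0.5)
    fm <- sim_training_fm(sim, "micro")
    loocv_svm(fm, sim_labels(sim), kernel_spec("linear"))$metrics$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 14 / 24), 0.10)
})

test_that("ROC staircase and AUC behave on the canonical cases", {
  labels <- c(1, 1, 1, -1, -1, -1)
  perfect <- roc_curve(c(3, 2.5, 2, 1, 0.5, 0), labels)
  expect_equal(attr(perfect, "auc"), 1)
  inverted <- roc_curve(c(0, 0.5, 1, 2, 2.5, 3), labels)
  expect_equal(attr(inverted, "auc"), 0)
  expect_true(all(diff(perfect$FPR) >= 0) && all(diff(perfect$TPR) >= 0))
  # tied scores collapse into one threshold step
  tied <- roc_curve(c(1, 1, 1, 1, 1, 1), labels)
  expect_equal(nrow(tied), 2)
  expect_equal(attr(tied, "auc"), 0.5)
})

test_that("AUC is invariant under monotone score transforms and null-centred", {
  set.seed(44)
  for (i in 1:10) {
    sc <- rnorm(40)
    lb <- ifelse(runif(40) > 0.5, 1, -1)
    if (length(unique(lb)) < 2) next
    a1 <- attr(roc_curve(sc, lb), "auc")
    expect_equal(attr(roc_curve(exp(2 * sc) + 5, lb), "auc"), a1)
  }
  aucs <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    attr(roc_curve(rnorm(40), rep(c(1, -1), 20)), "auc")
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("three-fold ROC is stratified, seeded and scores held-out genes", {
  sep <- make_separable(n_per_class = 9, d = 3, gap = 6, seed = 45)
  r <- roc_threefold(sep$X, sep$y, kernel_spec("rbf"), seed = 2)
  expect_length(r$folds, 3)
  expect_equal(r$auc_mean, 1)
  for (f in 1:3) {
    idx <- r$fold == f
    expect_true(all(table(sep$y[idx]) >= 1))
  }
  r2 <- roc_threefold(sep$X, sep$y, kernel_spec("rbf"), seed = 2)
  expect_identical(r$auc_mean, r2$auc_mean)
  expect_error(roc_threefold(sep$X[1:5, ], sep$y[1:5]), "at least 6")
})

test_that("rank correlation is Spearman with average-rank ties", {
  expect_equal(rank_correlation(1:10, 2 * (1:10) + 3), 1)
  expect_equal(rank_correlation(1:10, rev(1:10)), -1)
  set.seed(46)
  for (i in 1:10) {
    u <- sample(1:5, 20, replace = TRUE)  # forces ties
    v <- rnorm(20)
    expect_equal(rank_correlation(u, v),
                 stats::cor(u, v, method = "spearman"))
    expect_equal(rank_correlation(exp(u), v), rank_correlation(u, v))
  }
  expect_warning(r <- rank_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  expect_error(rank_correlation(1:3, 1:4), "equal length")
})

test_that("fisher_overlap equals the exhaustive hypergeometric tail", {
  expect_gt(fisher_overlap("a", "b", 1000), 0.99)
  ids <- sprintf("g%03d", 1:10)
  expect_equal(fisher_overlap(ids, ids, 100), 1 / choose(100, 10))
  A <- sprintf("g%03d", 1:10)
  B <- sprintf("g%03d", 6:15)  # overlap 5
  expect_equal(fisher_overlap(A, B, 100), brute_hyper_p(5, 10, 10, 100))
  set.seed(47)
  for (i in 1:10) {
    universe <- sprintf("u%03d", 1:60)
    A <- sample(universe, 12); B <- sample(universe, 9)
    ov <- length(intersect(A, B))
    expect_equal(fisher_overlap(A, B, 60), brute_hyper_p(ov, 12, 9, 60))
  }
  expect_error(fisher_overlap(sprintf("x%d", 1:5), sprintf("y%d", 1:6), 8),
               "universe")
})
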