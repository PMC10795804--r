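# Metrics, ROC/AUC and repeated stratified cross-validation.

test_that("confusion-count ratios follow their defining formulas", {
  m <- suppressWarnings(metrics_from_counts(c(TP = 3, FP = 0, TN = 0, FN = 1)))
  expect_equal(m[["TPR"]], 0.75)
  m2 <- metrics_from_counts(c(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(unname(m2[c("ACC", "TPR", "TNR", "precision")]), c(1, 1, 1, 1))
  m3 <- metrics_from_counts(c(TP = 2, FP = 2, TN = 1, FN = 1))
  expect_equal(m3[["precision"]], 0.5)
  expect_equal(m3[["ACC"]], 0.5)
  # zero denominators warn and give NA
  expect_warning(m4 <- metrics_from_counts(c(TP = 0, FP = 0, TN = 3, FN = 2)),
                 "precision")
  expect_true(is.na(m4[["precision"]]))
  expect_error(metrics_from_counts(c(TP = 0, FP = 0, TN = 0, FN = 0)),
               class = "hybridpcr_parameter_error")
  # ACC equals 1 - misclassification rate computed independently
  set.seed(2)
  truth <- sample(c("non-pCR", "pCR"), 40, replace = TRUE)
  pred <- sample(c("non-pCR", "pCR"), 40, replace = TRUE)
  cc <- confusion_counts(truth, pred)
  expect_equal(sum(cc), 40)
  expect_equal(suppressWarnings(metrics_from_counts(cc)[["ACC"]]),
               1 - mean(truth != pred))
})

test_that("trapezoidal AUC equals the pairwise rank oracle", {
  y <- c(rep("non-pCR", 4), rep("pCR", 4))
  expect_equal(auc_from_scores(y, c(1:4 / 10, 6:9 / 10)), 1)
  expect_equal(auc_from_scores(y, rep(0.3, 8)), 0.5)
  expect_error(auc_from_scores(rep("pCR", 4), runif(4)),
               class = "hybridpcr_parameter_error")
  set.seed(14)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    y <- sample(c("non-pCR", "pCR"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)  # coarse scores force ties
    expect_equal(auc_from_scores(y, s), oracle_auc(y, s), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  for (i in 1:5) {
    y <- sample(c("non-pCR", "pCR"), 30, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- runif(30)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = s, levels = c("non-pCR", "pCR"),
      direction = "<", quiet = TRUE)))
    expect_equal(auc_from_scores(y, s), ref, tolerance = 1e-10)
  }
})

test_that("ROC vertical averaging interpolates and preserves endpoints", {
  c1 <- data.frame(fpr = c(0, 0.5, 1), tpr = c(0, 1, 1))
  # identical curves average to themselves
  avg <- aggregate_roc(list(c1, c1), n_grid = 11)
  expect_equal(avg$tpr, stats::approx(c1$fpr, c1$tpr, xout = avg$fpr)$y)
  # two curves: pointwise mean against hand interpolation
  c2 <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
  avg2 <- aggregate_roc(list(c1, c2), n_grid = 5)
  hand <- (stats::approx(c1$fpr, c1$tpr, xout = c(0, .25, .5, .75, 1))$y +
           c(0, .25, .5, .75, 1)) / 2
  expect_equal(avg2$tpr, hand)
  expect_equal(avg2$tpr[1], 0)
  expect_equal(avg2$tpr[5], 1)
  # averaging monotone curves stays monotone
  set.seed(16)
  curves <- lapply(1:6, function(i) {
    y <- sample(c("non-pCR", "pCR"), 20, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("non-pCR", "pCR")
    roc_points(y, runif(20))
  })
  m <- aggregate_roc(curves)
  expect_true(all(diff(m$tpr) >= -1e-12))
})

test_that("stratified folds balance both classes, reproducibly", {
  labels <- rep(c("pCR", "non-pCR"), c(74, 64))
  f1 <- make_stratified_folds(labels, 5, seed = 7)
  f2 <- make_stratified_folds(labels, 5, seed = 7)
  expect_identical(f1, f2)
  sizes <- as.vector(table(f1))
  expect_equal(sort(sizes, decreasing = TRUE), c(28, 28, 28, 27, 27))
  per_class <- table(labels, f1)
  expect_lte(max(per_class["pCR", ]) - min(per_class["pCR", ]), 1)
  expect_lte(max(per_class["non-pCR", ]) - min(per_class["non-pCR", ]), 1)
  # every sample in exactly one test fold
  expect_true(all(f1 %in% 1:5))
  expect_length(f1, 138)
})

test_that("repeated CV is deterministic and near-perfect on separable data", {
  sim <- small_fit_data(n = 60, effect = 2.5, seed = 71)
  feats <- list(domain = sim$domain, abstract = sim$abstract)
  r1 <- run_repeated_cv(feats, sim$labels, n_folds = 3, n_repeats = 2,
                        base_seed = 9)
  r2 <- run_repeated_cv(feats, sim$labels, n_folds = 3, n_repeats = 2,
                        base_seed = 9)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$mean_roc, r2$mean_roc)
  expect_equal(nrow(r1$folds), 6)
  expect_gt(r1$summary$mean[r1$summary$metric == "AUC"], 0.95)
  expect_true(all(r1$summary$sd_fold >= 0))
  expect_output(print(r1), "Repeated stratified")
})

test_that("label-permuted data scores at chance level", {
  sim <- small_fit_data(n = 60, effect = 2, seed = 81)
  set.seed(99)
  perm_labels <- sample(sim$labels)
  rep_ <- run_repeated_cv(list(domain = sim$domain), perm_labels,
                          n_folds = 3, n_repeats = 3, base_seed = 13)
  auc <- rep_$summary$mean[rep_$summary$metric == "AUC"]
  expect_gt(auc, 0.3)
  expect_lt(auc, 0.7)
})
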