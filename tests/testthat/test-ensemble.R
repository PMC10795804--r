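# Ensemble weights, soft voting and the fitted hybrid classifier.

test_that("accuracy weighting follows the softmax-of-logit rule", {
  # equal accuracies -> uniform weights
  w8 <- compute_weights(rep(0.5, 8))
  expect_equal(w8$w, rep(1 / 8, 8), tolerance = 1e-12)
  w_same <- compute_weights(rep(0.9, 8))
  expect_equal(w_same$w, rep(1 / 8, 8), tolerance = 1e-12)
  # hand evaluation at m = 2, p = (0.8, 0.2)
  w2 <- compute_weights(c(0.8, 0.2))
  expect_equal(w2$x, c(log(4), -log(4)), tolerance = 1e-12)
  expect_equal(w2$w, c(16 / 17, 1 / 17), tolerance = 1e-12)
  # clipping keeps p = 1 finite and maximal
  wc <- compute_weights(c(1, 0.6))
  expect_true(all(is.finite(wc$w)))
  expect_gt(wc$w[1], wc$w[2])
  expect_equal(sum(wc$w), 1, tolerance = 1e-12)
  expect_error(compute_weights(c(0.5, 1.2)), class = "hybridpcr_parameter_error")
})

test_that("weights are monotone in accuracy and permutation-equivariant", {
  set.seed(10)
  for (i in 1:20) {
    p <- runif(8)
    w <- compute_weights(p)$w
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w > 0))
    expect_identical(order(w), order(p))  # strictly monotone
    perm <- sample(8)
    expect_equal(compute_weights(p[perm])$w, w[perm], tolerance = 1e-12)
  }
})

test_that("soft voting matches a loop oracle and stays a convex combination", {
  set.seed(20)
  for (i in 1:100) {
    m <- sample(2:8, 1)
    h <- t(apply(matrix(runif(2 * m), m), 1, function(r) r / sum(r)))
    w <- compute_weights(runif(m))$w
    f_loop <- c(0, 0)
    for (j in 1:2) for (k in 1:m) f_loop[j] <- f_loop[j] + w[k] * h[k, j]
    f_vec <- as.vector(t(h) %*% w)
    expect_equal(f_vec, f_loop, tolerance = 1e-12)
    expect_equal(sum(f_vec), 1, tolerance = 1e-9)
    for (j in 1:2) {
      expect_gte(f_vec[j], min(h[, j]) - 1e-12)
      expect_lte(f_vec[j], max(h[, j]) + 1e-12)
    }
  }
})

test_that("the fitted hybrid ensemble is deterministic and beats chance on signal", {
  sim <- small_fit_data(n = 80, effect = 1.2, seed = 31)
  feats <- list(domain = sim$domain, abstract = sim$abstract)
  f1 <- hybrid_pcr(feats, sim$labels, seed = 5)
  f2 <- hybrid_pcr(feats, sim$labels, seed = 5)
  expect_length(f1$members, 8)
  expect_equal(coef(f1), coef(f2))
  expect_true(all(f1$weights$p > 0.5))  # separable data: all members above chance
  p1 <- predict(f1, feats, type = "prob")
  p2 <- predict(f2, feats, type = "prob")
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, nrow(p1)), tolerance = 1e-9)
  # summary/print/coef surface
  s <- summary(f1)
  expect_s3_class(s, "summary.hybrid_pcr")
  expect_equal(nrow(s$members), 8)
  expect_output(print(f1), "hybrid pCR")
})

test_that("a single-member ensemble degenerates to that classifier", {
  sim <- small_fit_data(n = 60, effect = 1.5, seed = 41)
  fit <- hybrid_pcr(list(domain = sim$domain), sim$labels,
                    classifiers = "lr", seed = 3)
  expect_length(fit$members, 1)
  expect_equal(unname(fit$weights$w), 1)
  h <- predict_members(fit, list(domain = sim$domain))
  f <- predict(fit, list(domain = sim$domain), type = "prob")
  expect_equal(f[, "pCR"], h[, "pCR", 1], tolerance = 1e-12)
})

test_that("prediction honours the tie rule and rejects malformed input", {
  sim <- small_fit_data(n = 60, effect = 1, seed = 51)
  fit <- hybrid_pcr(list(domain = sim$domain), sim$labels, seed = 2)
  expect_error(predict(fit, list(domain = sim$domain[, 1:5])),
               class = "hybridpcr_shape_error")
  expect_error(predict(fit, list(wrong = sim$domain)),
               class = "hybridpcr_shape_error")
  # argmax with an exact tie resolves to non-pCR: p = 0.5 both
  # (constructed through the convex-combination contract)
  f <- matrix(0.5, 1, 2, dimnames = list(NULL, c("non-pCR", "pCR")))
  cls <- hybridpCR:::PCR_LEVELS[(f[, 2] > f[, 1]) + 1L]
  expect_identical(cls, "non-pCR")
})

test_that("chi-square selection inside the model keeps the requested width", {
  sim <- generate_feature_matrices(n = 70, d_domain = 30, d_abstract = 120,
                                   effect = 1, seed = 61)
  fit <- hybrid_pcr(list(abstract = sim$abstract), sim$labels,
                    select_k = c(abstract = 40), seed = 4)
  expect_length(fit$preproc$abstract$sel, 40)
  # prediction still works on full-width input
  pr <- predict(fit, list(abstract = sim$abstract))
  expect_s3_class(pr, "factor")
})
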