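# Backbone construction, multi-level pooling and chi-square selection.

reduced_plan <- function(in_size = 64L)
  backbone_plan(conv_counts = c(1, 1, 1, 1, 1), in_size = in_size)

test_that("the default plan yields a 1472-dimensional pooled vector", {
  plan <- backbone_plan()
  expect_equal(plan$widths, c(64L, 128L, 256L, 512L, 512L))
  expect_equal(sum(plan$pooled_dims), 1472L)
  bb <- build_backbone(reduced_plan(), seed = 4)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  f <- extract_multilevel(x, bb)
  expect_length(f, 1472L)
  expect_true(all(is.finite(f)))
  # stage tagging s1..s5 with the plan widths
  expect_equal(as.integer(table(substr(names(f), 1, 2))[paste0("s", 1:5)]),
               c(64L, 128L, 256L, 512L, 512L))
  expect_error(extract_multilevel(array(0, c(32, 32, 3)), bb),
               class = "hybridpcr_shape_error")
})

test_that("seeded backbones are reproducible and spatial sizes halve per stage", {
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  f1 <- extract_multilevel(x, build_backbone(reduced_plan(), seed = 9))
  f2 <- extract_multilevel(x, build_backbone(reduced_plan(), seed = 9))
  f3 <- extract_multilevel(x, build_backbone(reduced_plan(), seed = 10))
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  # a missing weights file warns and falls back to seeded random
  expect_warning(build_backbone(reduced_plan(), weights = "no/such/file.rds"),
                 "falling back")
  # spatial halving: maps after each pool are (32, 16, 8, 4, 2) for 64 input
  maps <- hybridpCR:::backbone_forward(build_backbone(reduced_plan(), seed = 9),
                                       x, keep_maps = TRUE)
  expect_equal(vapply(maps$maps, function(m) m$h, 0L), c(32L, 16L, 8L, 4L, 2L))
})

test_that("global average pooling equals a loop-based spatial mean", {
  bb <- build_backbone(reduced_plan(), seed = 2)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- hybridpCR:::backbone_forward(bb, x, keep_maps = TRUE)
  for (s in c(1, 3, 5)) {
    mp <- out$maps[[s]]
    loop_mean <- numeric(ncol(mp$act))
    for (ch in seq_len(ncol(mp$act))) {
      tot <- 0
      for (px in seq_len(nrow(mp$act))) tot <- tot + mp$act[px, ch]
      loop_mean[ch] <- tot / nrow(mp$act)
    }
    expect_equal(unname(out$pooled[[s]]), loop_mean, tolerance = 1e-12)
  }
})

test_that("chi-square scores follow the O/E formula and its symmetries", {
  # constant feature scores 0
  x <- cbind(const = rep(2, 10), informative = c(rep(0, 5), rep(1, 5)))
  y <- rep(c("non-pCR", "pCR"), each = 5)
  sc <- chi_square_scores(x, y)
  expect_equal(unname(sc$scores["const"]), 0)
  # binary feature equal to the class indicator, n = 10, 5/5:
  # scaled sums O = (0, 5), E = (2.5, 2.5) -> X2 = 2.5 + 2.5 = 5
  expect_equal(unname(sc$scores["informative"]), 5)
  # permuting samples changes nothing
  set.seed(8)
  perm <- sample(10)
  sc2 <- chi_square_scores(x[perm, ], y[perm])
  expect_equal(sc2$scores, sc$scores)
})

test_that("top-k selection keeps the largest scores with index tie-breaks", {
  expect_identical(select_top_k(c(3, 1, 2), k = 2), c(1L, 3L))
  expect_identical(sort(select_top_k(c(1, 1, 1, 1), k = 2)), c(1L, 2L))
  expect_identical(sort(select_top_k(c(5, 2, 9), k = 3)), 1:3)
  expect_error(select_top_k(c(1, 2), k = 3), class = "hybridpcr_parameter_error")
  # kept scores dominate dropped scores
  set.seed(5)
  s <- runif(40)
  kept <- select_top_k(s, 15)
  expect_gte(min(s[kept]), max(s[-kept]))
  # selection is stable across reruns
  x <- matrix(runif(200), 20, 10)
  y <- rep(c("non-pCR", "pCR"), 10)
  k1 <- select_top_k(chi_square_scores(x, y), 4)
  k2 <- select_top_k(chi_square_scores(x, y), 4)
  expect_identical(k1, k2)
})

test_that("head fine-tuning learns separable phantom slices and is optional", {
  bb <- build_backbone(reduced_plan(32L), seed = 6)
  set.seed(77)
  mk_slice <- function(cl) {
    base <- if (cl == "pCR") 0.75 else 0.25
    array(base + 0.05 * stats::rnorm(32 * 32), c(32, 32, 3))
  }
  labels <- rep(c("non-pCR", "pCR"), each = 6)
  slices <- lapply(labels, mk_slice)
  # epochs = 0 leaves the extractor untouched
  expect_identical(fine_tune(bb, slices, labels, epochs = 0), bb)
  ft <- fine_tune(bb, slices, labels, epochs = 60, lr = 0.5)
  pred <- predict_slices(ft, slices)
  expect_gt(mean(pred == labels), 0.5)  # above the majority-class rate
  # loss is non-increasing on average
  hist <- attr(ft, "history")
  expect_lt(mean(diff(hist)), 0)
  expect_error(fine_tune(bb, slices[1:6], labels[1:6], epochs = 1),
               class = "hybridpcr_training_error")
})
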