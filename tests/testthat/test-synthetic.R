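# Synthetic phantom, clinical-table and feature-matrix generators.

small_spec <- function(...) phantom_spec(grid_dim = c(24, 24, 10),
                                         spacing = c(1, 1, 3),
                                         semi_axes = c(7, 6, 9), ...)

test_that("phantoms are deterministic per seed and respect the grid", {
  sp <- small_spec()
  a <- generate_phantom(sp, "pCR", seed = 5)
  b <- generate_phantom(sp, "pCR", seed = 5)
  c_ <- generate_phantom(sp, "pCR", seed = 6)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  expect_false(identical(a$volume$voxels, c_$volume$voxels))
  expect_true(all(a$volume$voxels >= 0 & a$volume$voxels <= 1))
  expect_gt(sum(a$mask$voxels), 0)
  expect_error(phantom_spec(grid_dim = c(10, 10, 4), semi_axes = c(20, 5, 5)),
               class = "hybridpcr_parameter_error")
})

test_that("the class intensity shift is realised and vanishes at delta 0", {
  sp_eff <- small_spec(delta_mean = 0.3, delta_texture = 1)
  means <- function(spec, label, seeds) vapply(seeds, function(s) {
    ph <- generate_phantom(spec, label, seed = s)
    mean(ph$volume$voxels[ph$mask$voxels == 1])
  }, 0)
  m_pcr <- means(sp_eff, "pCR", 1:25)
  m_non <- means(sp_eff, "non-pCR", 101:125)
  expect_equal(mean(m_pcr) - mean(m_non), 0.3, tolerance = 0.05)

  sp_null <- small_spec(delta_mean = 0, delta_texture = 1)
  m_pcr0 <- means(sp_null, "pCR", 1:25)
  m_non0 <- means(sp_null, "non-pCR", 101:125)
  diff0 <- mean(m_pcr0) - mean(m_non0)
  se <- sqrt(stats::var(m_pcr0) / 25 + stats::var(m_non0) / 25)
  expect_lt(abs(diff0), 3 * se + 1e-8)
})

test_that("texture contrast differs between classes when delta_texture > 1", {
  sp <- small_spec(delta_mean = 0, delta_texture = 2.5)
  contrast <- function(label, s) {
    ph <- generate_phantom(sp, label, seed = s)
    vol <- normalize_intensity(ph$volume)
    q <- discretize(vol, ph$mask, 16)
    glcm_features(q)[["Contrast"]]
  }
  c_pcr <- vapply(1:8, function(s) contrast("pCR", s), 0)
  c_non <- vapply(101:108, function(s) contrast("non-pCR", s), 0)
  # smoother field (larger correlation length) -> lower co-occurrence contrast
  expect_lt(mean(c_pcr), mean(c_non))
})

test_that("clinical tables match the requested marginals and seed exactly", {
  t1 <- generate_clinical_table(seed = 4)
  t2 <- generate_clinical_table(seed = 4)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 138)
  expect_equal(sum(t1$pcr_label == "pCR"), 74)
  # tumor-diameter >= 4 cm fraction close to the published 73% / 75%
  frac_pcr <- mean(t1$tumor_diameter[t1$pcr_label == "pCR"] == ">=4")
  frac_non <- mean(t1$tumor_diameter[t1$pcr_label == "non-pCR"] == ">=4")
  expect_equal(frac_pcr, 54 / 74, tolerance = 0.01)
  expect_equal(frac_non, 48 / 64, tolerance = 0.01)
  expect_true(all(t1$age >= 25 & t1$age <= 65))
  # degenerate proportions give a constant column
  pr <- hybridpCR:::default_clinical_proportions()
  pr$lymph_node$pCR <- c(negative = 1, positive = 0)
  pr$lymph_node$`non-pCR` <- c(negative = 1, positive = 0)
  t3 <- generate_clinical_table(10, 10, proportions = pr, seed = 1)
  expect_true(all(t3$lymph_node == "negative"))
  pr$lymph_node$pCR <- c(negative = 0.5, positive = 0.4)
  expect_error(generate_clinical_table(10, 10, proportions = pr),
               class = "hybridpcr_parameter_error")
})

test_that("feature matrices share labels, order and the requested effect", {
  s0 <- generate_feature_matrices(n = 50, effect = 0, seed = 3)
  s1 <- generate_feature_matrices(n = 50, effect = 2, seed = 3)
  expect_identical(dim(s0$domain), c(50L, 114L))
  expect_identical(dim(s0$abstract), c(50L, 95L))
  expect_identical(s0$labels, s1$labels)
  # informative columns shifted by ~effect for the pCR class
  inf_cols <- 1:round(0.2 * 114)
  shift <- mean(s1$domain[s1$labels == "pCR", inf_cols]) -
    mean(s1$domain[s1$labels == "non-pCR", inf_cols])
  expect_equal(shift, 2, tolerance = 0.15)
  null_shift <- mean(s0$domain[s0$labels == "pCR", inf_cols]) -
    mean(s0$domain[s0$labels == "non-pCR", inf_cols])
  expect_lt(abs(null_shift), 0.15)
  expect_error(generate_feature_matrices(n = 2), class = "hybridpcr_parameter_error")
})
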