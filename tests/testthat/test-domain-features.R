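# Discretisation, first-order, shape and the assembled domain vector.

test_that("equal-width discretisation follows the half-open bin rule", {
  v <- image_volume(array(c(0, 0.5, 1.0, 0, 0, 0, 0, 0), c(2, 2, 2)))
  m <- array(0, c(2, 2, 2)); m[1:3] <- 1
  q <- discretize(v, roi_mask(m), n_bins = 2)
  expect_identical(q$levels[!is.na(q$levels)], c(1L, 2L, 2L))
  expect_identical(q$n_levels, 2L)

  # constant ROI collapses to one level
  qc <- discretize(image_volume(array(0.4, c(2, 2, 2))),
                   roi_mask(array(1, c(2, 2, 2))), n_bins = 8)
  expect_identical(qc$n_levels, 1L)
  expect_true(all(qc$levels == 1L))

  # the maximum never lands in a phantom top bin
  set.seed(3)
  vr <- image_volume(array(runif(27), c(3, 3, 3)))
  qr <- discretize(vr, roi_mask(array(1, c(3, 3, 3))), n_bins = 7)
  expect_lte(max(qr$levels), 7L)
  expect_gte(min(qr$levels), 1L)
  expect_error(discretize(vr, roi_mask(array(1, c(3, 3, 3))), n_bins = 1),
               class = "hybridpcr_parameter_error")
})

test_that("first-order features match closed forms", {
  v <- image_volume(array(c(1, 2, 3, 4, 0, 0, 0, 0), c(2, 2, 2)))
  m <- array(0, c(2, 2, 2)); m[1:4] <- 1
  fo <- first_order_features(v, roi_mask(m), n_bins = 4)
  expect_equal(fo[["Mean"]], 2.5)
  expect_equal(fo[["Energy"]], 30)
  expect_equal(fo[["Minimum"]], 1)
  expect_equal(fo[["Maximum"]], 4)
  expect_equal(fo[["Range"]], 3)
  expect_equal(fo[["Variance"]], 1.25)   # population variance
  # four equal-count bins -> 2 bits of histogram entropy, uniformity 1/4
  expect_equal(fo[["Entropy"]], 2)
  expect_equal(fo[["Uniformity"]], 0.25)

  # constant ROI degenerates gracefully
  fc <- first_order_features(image_volume(array(2, c(2, 2, 2))),
                             roi_mask(array(1, c(2, 2, 2))))
  expect_equal(fc[["Variance"]], 0)
  expect_equal(fc[["Skewness"]], 0)
  expect_equal(fc[["Uniformity"]], 1)
})

test_that("shape features are exact on a solid cube", {
  m <- array(0, c(7, 7, 7)); m[3:5, 3:5, 3:5] <- 1
  sf <- shape_features(roi_mask(m))
  expect_equal(sf[["VoxelVolume"]], 27)
  expect_equal(sf[["Elongation"]], 1)
  expect_equal(sf[["Flatness"]], 1)
  expect_equal(sf[["Maximum3DDiameter"]], 2 * sqrt(3), tolerance = 1e-12)
  # anisotropic spacing scales the voxel volume
  sf2 <- shape_features(roi_mask(m, spacing = c(1, 1, 3)))
  expect_equal(sf2[["VoxelVolume"]], 81)
})

test_that("sphericity of digitised balls increases monotonically toward 1", {
  sph <- vapply(c(5, 8, 12), function(rad) {
    n <- 2 * rad + 7; cc <- (n + 1) / 2
    arr <- array(0L, c(n, n, n))
    idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
    arr[rowSums((idx - cc)^2) <= rad^2] <- 1L
    shape_features(roi_mask(arr))[["Sphericity"]]
  }, 0)
  expect_true(all(diff(sph) > 0))
  expect_gt(sph[3], 0.98)
  expect_lt(sph[3], 1)
  # and the mesh volume approaches the analytic ball volume
  rad <- 12; n <- 31; cc <- 16
  arr <- array(0L, c(n, n, n))
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  arr[rowSums((idx - cc)^2) <= rad^2] <- 1L
  sv <- mesh_surface_and_volume(roi_mask(arr))
  expect_equal(sv$volume, 4 / 3 * pi * rad^3, tolerance = 0.05)
  expect_equal(sv$area, 4 * pi * rad^2, tolerance = 0.05)
})

test_that("the domain vector has catalogue length, is deterministic and finite", {
  ph <- blob_phantom(seed = 21)
  vol <- normalize_intensity(ph$volume)
  dv1 <- extract_domain_vector(vol, ph$mask)
  dv2 <- extract_domain_vector(vol, ph$mask)
  expect_length(dv1, 107)
  expect_true(all(is.finite(dv1)))
  expect_identical(unclass(dv1), unclass(dv2))
  expect_identical(attr(dv1, "catalogue_id"), "ibsi-standard-107")
  # catalogue family sizes
  cat_df <- feature_catalogue()
  expect_equal(as.integer(table(cat_df$family)[c("shape", "firstorder", "glcm",
                                                 "glrlm", "glszm", "gldm", "ngtdm")]),
               c(14L, 18L, 24L, 16L, 16L, 14L, 5L))
  expect_error(extract_domain_vector(vol, roi_mask(array(0, dim(vol$voxels)),
                                                   spacing = vol$spacing)),
               class = "hybridpcr_empty_roi_error")
})

test_that("intensity and texture features are invariant to ROI translation", {
  ph <- blob_phantom(dim3 = c(20, 20, 8), seed = 33)
  vol <- normalize_intensity(ph$volume)
  dv <- extract_domain_vector(vol, ph$mask)
  # shift the whole phantom by (3, 2, 1) voxels inside a larger grid
  big <- c(28, 28, 12)
  shift <- c(3, 2, 1)
  vox2 <- array(0, big); msk2 <- array(0, big)
  vox2[shift[1] + 1:20, shift[2] + 1:20, shift[3] + 1:8] <- vol$voxels
  msk2[shift[1] + 1:20, shift[2] + 1:20, shift[3] + 1:8] <- ph$mask$voxels
  dv2 <- extract_domain_vector(image_volume(vox2, vol$spacing),
                               roi_mask(msk2, vol$spacing))
  non_positional <- setdiff(names(dv), character(0))
  expect_equal(dv[non_positional], dv2[non_positional], tolerance = 1e-10)
})
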