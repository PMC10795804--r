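# Volume IO, resampling, normalisation and tumor-slice preparation.

test_that("NIfTI volume/mask pairs round-trip and misalignments are rejected", {
  ph <- blob_phantom()
  td <- withr::local_tempdir()
  vp <- file.path(td, "vol.nii.gz"); mp <- file.path(td, "mask.nii.gz")
  write_volume(ph$volume, vp)
  write_volume(ph$mask, mp)
  pair <- load_volume_and_mask(vp, mp)
  expect_equal(pair$volume$voxels, ph$volume$voxels, tolerance = 1e-6)
  expect_identical(pair$mask$voxels, ph$mask$voxels)
  expect_equal(pair$volume$spacing, c(1, 1, 3))

  # grid mismatch
  small <- image_volume(array(0, c(8, 8, 4)))
  sp <- file.path(td, "small.nii.gz")
  write_volume(small, sp)
  expect_error(load_volume_and_mask(vp, sp), class = "hybridpcr_alignment_error")

  # empty mask
  em <- roi_mask(array(0, dim(ph$mask$voxels)), spacing = ph$mask$spacing)
  ep <- file.path(td, "empty.nii.gz")
  write_volume(em, ep)
  expect_error(load_volume_and_mask(vp, ep), class = "hybridpcr_empty_roi_error")
})

test_that("resampling follows the grid-size formula and preserves mask labels", {
  v <- image_volume(array(stats::rnorm(100 * 60 * 10), c(100, 60, 10)),
                    spacing = c(1, 1, 3))
  r <- resample(v, c(0.5, 0.5, 3))
  expect_identical(dim(r$voxels), c(200L, 120L, 10L))
  expect_equal(r$spacing, c(0.5, 0.5, 3))

  # identity resampling
  r0 <- resample(v, v$spacing)
  expect_equal(r0$voxels, v$voxels, tolerance = 1e-12)

  # nearest-neighbour keeps a mask binary
  m <- roi_mask(array(rbinom(8 * 8 * 4, 1, 0.4), c(8, 8, 4)), spacing = c(2, 2, 3))
  rm_ <- resample(m, c(0.9, 0.9, 2), "nearest")
  expect_true(all(rm_$voxels %in% c(0, 1)))
  expect_error(resample(m, c(1, 1, 1), "linear"), class = "hybridpcr_parameter_error")
  expect_error(resample(v, c(0, 1, 1)), class = "hybridpcr_parameter_error")
})

test_that("down-up resampling a smooth phantom is close to the original", {
  ph <- blob_phantom(seed = 5)
  down <- resample(ph$volume, c(0.5, 0.5, 3))
  back <- resample(down, c(1, 1, 3))
  expect_identical(dim(back$voxels), dim(ph$volume$voxels))
  err <- mean(abs(back$voxels - ph$volume$voxels))
  expect_lt(err, 0.03)
})

test_that("intensity normalisation is a monotone idempotent map to [0, 1]", {
  v <- image_volume(array(c(0, 5, 10, 2, 7, 3, 9, 1), c(2, 2, 2)))
  nv <- normalize_intensity(v)
  expect_equal(range(nv$voxels), c(0, 1))
  expect_equal(nv$voxels[1, 1, 1], 0)
  expect_equal(nv$voxels[1, 2, 1], 1)   # value 10
  expect_equal(nv$voxels[2, 1, 1], 0.5) # value 5
  # ordering preserved
  expect_identical(order(v$voxels), order(nv$voxels))
  # idempotent
  expect_equal(normalize_intensity(nv)$voxels, nv$voxels)
  # constant volume maps to zeros
  cv <- normalize_intensity(image_volume(array(3, c(2, 2, 2))))
  expect_true(all(cv$voxels == 0))
})

test_that("largest-ROI slice selection takes the first maximal slice", {
  m <- array(0, c(4, 4, 3))
  m[1:3, 1, 1] <- 1          # area 3
  m[1:4, 1:2, 2] <- 1        # area 8 - but make slice 2 and 3 tie
  m[1:4, 3:4, 3] <- 1        # area 8
  expect_identical(select_largest_roi_slice(roi_mask(m)), 2L)
  one <- array(0, c(3, 3, 4)); one[2, 2, 3] <- 1
  expect_identical(select_largest_roi_slice(roi_mask(one)), 3L)
  expect_error(select_largest_roi_slice(roi_mask(array(0, c(2, 2, 2)))),
               class = "hybridpcr_empty_roi_error")
})

test_that("crop-and-resize yields a 224x224x3 slice with identical channels", {
  ph <- blob_phantom()
  k <- select_largest_roi_slice(ph$mask)
  sl <- crop_and_resize(ph$volume$voxels[, , k], ph$mask$voxels[, , k])
  expect_identical(dim(sl$pixels), c(224L, 224L, 3L))
  expect_identical(sl$pixels[, , 1], sl$pixels[, , 2])
  expect_identical(sl$pixels[, , 1], sl$pixels[, , 3])
  # bilinear output bounded by the input crop
  bb <- sl$provenance$bbox
  crop <- ph$volume$voxels[bb[1]:bb[2], bb[3]:bb[4], k]
  expect_gte(min(sl$pixels), min(crop) - 1e-12)
  expect_lte(max(sl$pixels), max(crop) + 1e-12)

  # constant tumor region stays constant
  vs <- matrix(0.7, 10, 10); ms <- matrix(0, 10, 10); ms[3:7, 4:8] <- 1
  cs <- crop_and_resize(vs, ms, out_size = 32)
  expect_true(all(abs(cs$pixels - 0.7) < 1e-12))
  expect_error(crop_and_resize(vs, matrix(0, 10, 10)),
               class = "hybridpcr_empty_roi_error")
})

test_that("crop-and-resize commutes with global intensity scaling", {
  ph <- blob_phantom(seed = 9)
  k <- select_largest_roi_slice(ph$mask)
  a <- crop_and_resize(ph$volume$voxels[, , k] * 3.7, ph$mask$voxels[, , k],
                       out_size = 48)
  b <- crop_and_resize(ph$volume$voxels[, , k], ph$mask$voxels[, , k],
                       out_size = 48)
  expect_equal(a$pixels, b$pixels * 3.7, tolerance = 1e-12)
})
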