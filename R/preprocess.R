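#' Resample a volume to a new voxel spacing
#'
#' Resamples onto the target grid whose size per axis is
#' `round(old_size * old_spacing / new_spacing)` (half away from zero).
#' Voxel centres are aligned at the volume origin: output voxel `i`
#' (0-based) samples the input at physical offset `i * new_spacing`.
#' Images use trilinear interpolation; masks must use `"nearest"`, which
#' preserves the binary label set.
#'
#' @param vol an `image_volume` (or `roi_mask` with `interpolation = "nearest"`).
#' @param target_spacing numeric length-3 target voxel size in mm (default
#'   the 0.5 x 0.5 x 3 mm analysis grid).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return a resampled object of the same class as `vol`.
#' @export
resample <- function(vol, target_spacing = c(0.5, 0.5, 3),
                     interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop_hybridpcr("target_spacing must be 3 positive numbers", "hybridpcr_parameter_error")
  if (inherits(vol, "roi_mask") && interpolation != "nearest")
    stop_hybridpcr("masks must be resampled with nearest-neighbor interpolation",
                   "hybridpcr_parameter_error")
  old_dim <- dim(vol$voxels)
  new_dim <- pmax(1L, as.integer(round_half_up(old_dim * vol$spacing / target_spacing)))

  # fractional input coordinates (0-based) of each output voxel centre per axis
  coords <- lapply(1:3, function(a) {
    u <- (seq_len(new_dim[a]) - 1) * target_spacing[a] / vol$spacing[a]
    pmin(pmax(u, 0), old_dim[a] - 1)
  })

  vox <- vol$voxels
  if (interpolation == "nearest") {
    idx <- lapply(1:3, function(a) as.integer(floor(coords[[a]] + 0.5)) + 1L)
    out <- vox[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    i0 <- lapply(1:3, function(a) pmin(floor(coords[[a]]), old_dim[a] - 1))
    fr <- lapply(1:3, function(a) coords[[a]] - i0[[a]])
    i0 <- lapply(i0, function(v) as.integer(v) + 1L)
    i1 <- lapply(1:3, function(a) pmin(i0[[a]] + 1L, old_dim[a]))
    out <- array(0, new_dim)
    gx <- rep(seq_len(new_dim[1]), times = new_dim[2] * new_dim[3])
    gy <- rep(rep(seq_len(new_dim[2]), each = new_dim[1]), times = new_dim[3])
    gz <- rep(seq_len(new_dim[3]), each = new_dim[1] * new_dim[2])
    acc <- numeric(prod(new_dim))
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      wx <- if (cx == 0) 1 - fr[[1]] else fr[[1]]
      wy <- if (cy == 0) 1 - fr[[2]] else fr[[2]]
      wz <- if (cz == 0) 1 - fr[[3]] else fr[[3]]
      ix <- if (cx == 0) i0[[1]] else i1[[1]]
      iy <- if (cy == 0) i0[[2]] else i1[[2]]
      iz <- if (cz == 0) i0[[3]] else i1[[3]]
      w <- wx[gx] * wy[gy] * wz[gz]
      acc <- acc + w * vox[cbind(ix[gx], iy[gy], iz[gz])]
    }
    out <- array(acc, new_dim)
  }
  res <- vol
  res$voxels <- out
  res$spacing <- target_spacing
  res
}

#' Min-max normalise a volume's intensities to [0, 1]
#'
#' Rescales over the whole volume: `v' = (v - min) / (max - min)`. A constant
#' volume maps to all zeros to avoid 0/0. The map is monotone, so voxel
#' ordering is preserved, and it is idempotent.
#'
#' @param vol an `image_volume`.
#' @return the normalised `image_volume`.
#' @export
normalize_intensity <- function(vol) {
  v <- vol$voxels
  rng <- range(v)
  vol$voxels <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else array(0, dim(v))
  vol
}

#' Index of the axial slice with the largest tumor cross-section
#'
#' Scans the third (through-plane) axis and returns the 1-based index of the
#' slice with the most mask foreground voxels; ties go to the lowest index.
#'
#' @param mask a non-empty `roi_mask`.
#' @return integer slice index.
#' @export
select_largest_roi_slice <- function(mask) {
  check_roi_nonempty(mask)
  areas <- apply(mask$voxels, 3, sum)
  which.max(areas) # which.max already returns the first maximum
}

#' Crop the tumor region of a slice and resize it to the network input
#'
#' Takes the tight bounding box of the mask foreground on one axial slice
#' (optionally padded by `margin` voxels, clipped to the slice), resizes the
#' cropped patch with bilinear interpolation to `out_size` x `out_size`, and
#' replicates it to three identical channels as expected by the
#' convolutional feature extractor.
#'
#' @param vol_slice 2D numeric matrix (one axial slice of the image).
#' @param mask_slice 2D binary matrix of the same shape.
#' @param out_size output side length in pixels (default 224).
#' @param margin extra voxels of context around the bounding box (default 0).
#' @param provenance optional list (patient id, slice index) carried along.
#' @return a `preproc_slice`: list with `pixels` (`out_size x out_size x 3`)
#'   and `provenance` (including the bounding box used).
#' @export
crop_and_resize <- function(vol_slice, mask_slice, out_size = 224L, margin = 0L,
                            provenance = list()) {
  vol_slice <- as.matrix(vol_slice); mask_slice <- as.matrix(mask_slice)
  if (!identical(dim(vol_slice), dim(mask_slice)))
    stop_hybridpcr("slice and mask slice shapes differ", "hybridpcr_alignment_error")
  fg <- which(mask_slice > 0, arr.ind = TRUE)
  if (nrow(fg) == 0)
    stop_hybridpcr("mask slice has no foreground", "hybridpcr_empty_roi_error")
  r0 <- max(1L, min(fg[, 1]) - margin); r1 <- min(nrow(vol_slice), max(fg[, 1]) + margin)
  c0 <- max(1L, min(fg[, 2]) - margin); c1 <- min(ncol(vol_slice), max(fg[, 2]) + margin)
  crop <- vol_slice[r0:r1, c0:c1, drop = FALSE]
  resized <- resize_bilinear(crop, out_size, out_size)
  structure(list(
    pixels = array(resized, c(out_size, out_size, 3L)),
    provenance = c(provenance, list(bbox = c(r0, r1, c0, c1)))
  ), class = "preproc_slice")
}

# bilinear resize of a matrix with corner-aligned sampling; a 1-pixel axis
# degenerates to constant replication
resize_bilinear <- function(m, out_r, out_c) {
  in_r <- nrow(m); in_c <- ncol(m)
  u <- if (in_r == 1L) rep(0, out_r) else (seq_len(out_r) - 1) * (in_r - 1) / (out_r - 1)
  v <- if (in_c == 1L) rep(0, out_c) else (seq_len(out_c) - 1) * (in_c - 1) / (out_c - 1)
  r0 <- pmin(floor(u), in_r - 1); fr <- u - r0
  c0 <- pmin(floor(v), in_c - 1); fc <- v - c0
  r0 <- as.integer(r0) + 1L; r1 <- pmin(r0 + 1L, in_r)
  c0 <- as.integer(c0) + 1L; c1 <- pmin(c0 + 1L, in_c)
  wr1 <- fr; wr0 <- 1 - fr
  wc1 <- fc; wc0 <- 1 - fc
  (wr0 * m[r0, c0, drop = FALSE] + wr1 * m[r1, c0, drop = FALSE]) %*% diag(wc0, out_c) +
    (wr0 * m[r0, c1, drop = FALSE] + wr1 * m[r1, c1, drop = FALSE]) %*% diag(wc1, out_c)
}

#' Full slice preparation for abstract-feature extraction
#'
#' Convenience wrapper: picks the largest-ROI axial slice, crops to the
#' tumor bounding box, and resizes to the backbone input.
#'
#' @inheritParams crop_and_resize
#' @param vol a normalised `image_volume`.
#' @param mask the paired `roi_mask`.
#' @return a `preproc_slice`.
#' @export
prepare_tumor_slice <- function(vol, mask, out_size = 224L, margin = 0L,
                                provenance = list()) {
  k <- select_largest_roi_slice(mask)
  crop_and_resize(vol$voxels[, , k], mask$voxels[, , k],
                  out_size = out_size, margin = margin,
                  provenance = c(provenance, list(slice_index = k)))
}
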