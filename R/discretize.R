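#' Discretise ROI intensities into equal-width gray levels
#'
#' Bins the intensities inside the ROI into `n_bins` equal-width levels over
#' `[roi_min, roi_max]`. Level of a voxel with value v is
#' `floor((v - roi_min) / width) + 1`, with the ROI maximum assigned to the
#' top bin (never to a phantom level `G + 1`). A constant ROI collapses to a
#' single level (`G = 1`).
#'
#' @param vol an `image_volume`.
#' @param mask the paired `roi_mask` (non-empty).
#' @param n_bins number of gray levels (>= 2; default 32).
#' @return a `quantized_volume`: list with `levels` (3D integer array, `NA`
#'   outside the ROI), `n_levels` (G), and the grid `spacing`.
#' @export
discretize <- function(vol, mask, n_bins = 32L) {
  check_roi_nonempty(mask)
  if (!identical(dim(vol$voxels), dim(mask$voxels)))
    stop_hybridpcr("volume and mask shapes differ", "hybridpcr_alignment_error")
  if (n_bins < 2L)
    stop_hybridpcr("n_bins must be >= 2", "hybridpcr_parameter_error")
  inroi <- mask$voxels > 0
  v <- vol$voxels[inroi]
  rng <- range(v)
  lv <- array(NA_integer_, dim(vol$voxels))
  if (rng[2] > rng[1]) {
    width <- (rng[2] - rng[1]) / n_bins
    lev <- pmin(as.integer(floor((v - rng[1]) / width)) + 1L, as.integer(n_bins))
    g <- as.integer(n_bins)
  } else {
    lev <- rep(1L, length(v))
    g <- 1L
  }
  lv[inroi] <- lev
  structure(list(levels = lv, n_levels = g, spacing = vol$spacing),
            class = "quantized_volume")
}
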