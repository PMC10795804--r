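#' Image volume and ROI mask containers
#'
#' `image_volume()` wraps a 3D voxel array together with its grid geometry
#' (voxel spacing and origin, both in millimetres). `roi_mask()` is the
#' matching container for a binary tumor mask defined on the same grid.
#' These are deliberately light S3 records: all heavy lifting is done by the
#' preprocessing and feature-extraction functions that consume them.
#'
#' @param voxels 3D numeric array of intensities (mask: values in \{0, 1\}).
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, position of the first voxel centre in mm.
#' @return An object of class `image_volume` or `roi_mask`.
#' @examples
#' v <- image_volume(array(runif(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 3))
#' dim(v$voxels)
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L || length(voxels) == 0L)
    stop_hybridpcr("voxels must be a non-empty 3D array", "hybridpcr_parameter_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_hybridpcr("spacing must be 3 positive numbers (mm)", "hybridpcr_parameter_error")
  structure(list(voxels = voxels, spacing = spacing, origin = as.numeric(origin)),
            class = "image_volume")
}

#' @rdname image_volume
#' @export
roi_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop_hybridpcr("mask voxels must be a 3D array", "hybridpcr_parameter_error")
  if (!is_binary01(voxels))
    stop_hybridpcr("mask voxels must contain only 0 and 1", "hybridpcr_parameter_error")
  out <- image_volume(voxels, spacing, origin)
  class(out) <- c("roi_mask", "image_volume")
  out
}

#' @export
print.image_volume <- function(x, ...) {
  kind <- if (inherits(x, "roi_mask")) "ROI mask" else "Image volume"
  cat(sprintf("%s: %s voxels, spacing %s mm\n", kind,
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = " x ")))
  if (inherits(x, "roi_mask")) {
    cat(sprintf("  foreground voxels: %d\n", sum(x$voxels)))
  } else {
    cat(sprintf("  intensity range: [%.4g, %.4g]\n",
                min(x$voxels), max(x$voxels)))
  }
  invisible(x)
}

check_roi_nonempty <- function(mask) {
  if (sum(mask$voxels) == 0)
    stop_hybridpcr("ROI mask has no foreground voxels", "hybridpcr_empty_roi_error")
  invisible(TRUE)
}

#' Read a paired MRI volume and tumor mask from NIfTI files
#'
#' Reads the image and its tumor (GTV) mask, checks that the two files live
#' on the same grid (shape and spacing), and returns them as a paired
#' (`image_volume`, `roi_mask`) list. Mask voxels may be stored with any
#' positive label; they are binarised as `> 0`.
#'
#' @param volume_path path to the image NIfTI (.nii or .nii.gz).
#' @param mask_path path to the mask NIfTI on the identical grid.
#' @return list with elements `volume` and `mask`.
#' @export
load_volume_and_mask <- function(volume_path, mask_path) {
  if (!file.exists(volume_path))
    stop_hybridpcr(paste("volume file not found:", volume_path), "hybridpcr_io_error")
  if (!file.exists(mask_path))
    stop_hybridpcr(paste("mask file not found:", mask_path), "hybridpcr_io_error")
  vimg <- RNifti::readNifti(volume_path)
  mimg <- RNifti::readNifti(mask_path)
  varr <- drop(as.array(vimg)); marr <- drop(as.array(mimg))
  varr <- array(as.numeric(varr), dim(varr))
  marr <- array(as.numeric(marr), dim(marr))
  if (length(dim(varr)) != 3L || length(dim(marr)) != 3L)
    stop_hybridpcr("expected 3D NIfTI images", "hybridpcr_io_error")
  vsp <- RNifti::pixdim(vimg)[1:3]; msp <- RNifti::pixdim(mimg)[1:3]
  if (!identical(dim(varr), dim(marr)))
    stop_hybridpcr("volume and mask grid shapes differ", "hybridpcr_alignment_error")
  if (any(abs(vsp - msp) > 1e-4))
    stop_hybridpcr("volume and mask voxel spacings differ", "hybridpcr_alignment_error")
  mask <- roi_mask((marr > 0) + 0, spacing = vsp)
  check_roi_nonempty(mask)
  list(volume = image_volume(varr, spacing = vsp), mask = mask)
}

#' Write a volume or mask to NIfTI
#'
#' @param vol an `image_volume` or `roi_mask`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
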