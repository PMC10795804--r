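# Shared in-code fixtures.

# smooth Gaussian-blob phantom with an ellipsoidal mask
blob_phantom <- function(dim3 = c(24, 24, 8), spacing = c(1, 1, 3), seed = 42) {
  set.seed(seed)
  cc <- (dim3 - 1) / 2
  idx <- as.matrix(expand.grid(seq_len(dim3[1]), seq_len(dim3[2]), seq_len(dim3[3])))
  r2 <- ((idx[, 1] - 1 - cc[1]) / (dim3[1] / 3))^2 +
    ((idx[, 2] - 1 - cc[2]) / (dim3[2] / 3))^2 +
    ((idx[, 3] - 1 - cc[3]) / (dim3[3] / 3))^2
  vox <- array(exp(-r2) + 0.02 * stats::rnorm(prod(dim3)), dim3)
  mask <- array((r2 <= 1) + 0, dim3)
  list(volume = image_volume(vox, spacing), mask = roi_mask(mask, spacing))
}

small_fit_data <- function(n = 60, effect = 1.5, seed = 11) {
  generate_feature_matrices(n = n, d_domain = 20, d_abstract = 15,
                            effect = effect, seed = seed)
}
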