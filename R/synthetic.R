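# Synthetic phantom cohorts.
#
# The generators emulate the study conditions the pipeline was designed
# for: a two-class (pCR / non-pCR) cohort of 138 patients (74 / 64), T2-like
# tumor volumes with class-dependent intensity and texture structure, and a
# clinical table whose category proportions mirror the published cohort.
# All generators are pure functions of their seed and parameters.

# separable 3D Gaussian smoothing with reflected padding; sigma in voxels
gauss_smooth3d <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    n <- dim(arr)[ax]
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(arr, perm)
    d <- dim(a)
    m <- matrix(a, d[1], d[2] * d[3])
    idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - seq_len(min(r, n)))
    while (length(idx) < n + 2 * r) idx <- c(idx[1], idx, idx[length(idx)])
    mp <- m[idx, , drop = FALSE]
    sm <- matrix(0, d[1], d[2] * d[3])
    for (t in seq_along(k))
      sm <- sm + k[t] * mp[t:(t + n - 1), , drop = FALSE]
    arr <- aperm(array(sm, d), order(perm))
  }
  arr
}

#' Phantom specification
#'
#' Defines the synthetic tumor phantom: grid geometry, ellipsoidal ROI, and
#' the class effects. `delta_mean` shifts the mean ROI intensity of the pCR
#' class on the `[0, 1]` scale; `delta_texture` multiplies the correlation
#' length of the pCR class's Gaussian-field texture (1 = no texture
#' difference).
#'
#' @param grid_dim voxel grid (default `c(64, 64, 16)`).
#' @param spacing voxel size in mm (default `c(1, 1, 3)`, coarser than the
#'   0.5 x 0.5 x 3 mm analysis grid so that resampling is exercised).
#' @param semi_axes ellipsoid semi-axes in mm (default `c(15, 12, 9)`).
#' @param delta_mean class intensity shift (default 0.2).
#' @param delta_texture class correlation-length ratio (default 1.5).
#' @param texture_sd standard deviation of the ROI texture field (default 0.08).
#' @param corr_length base correlation length in mm (default 2).
#' @param noise_sd background noise sd (default 0.05).
#' @param base_mean mean ROI intensity of the non-pCR class (default 0.45).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_dim = c(64, 64, 16), spacing = c(1, 1, 3),
                         semi_axes = c(15, 12, 9), delta_mean = 0.2,
                         delta_texture = 1.5, texture_sd = 0.08,
                         corr_length = 2, noise_sd = 0.05, base_mean = 0.45) {
  centre_mm <- (grid_dim - 1) * spacing / 2
  if (any(semi_axes >= centre_mm))
    stop_hybridpcr("ROI semi-axes must fit inside the grid",
                   "hybridpcr_parameter_error")
  structure(list(grid_dim = as.integer(grid_dim), spacing = spacing,
                 semi_axes = semi_axes, delta_mean = delta_mean,
                 delta_texture = delta_texture, texture_sd = texture_sd,
                 corr_length = corr_length, noise_sd = noise_sd,
                 base_mean = base_mean),
            class = "phantom_spec")
}

#' Generate one phantom volume and its tumor mask
#'
#' The ROI is a centred ellipsoid filled with a smoothed Gaussian random
#' field: mean `base_mean` (+ `delta_mean` for the pCR class), sd
#' `texture_sd`, correlation length `corr_length` mm (x `delta_texture` for
#' the pCR class). Outside the ROI the volume is background noise around
#' 0.15. Intensities are clipped to `[0, 1]`. Deterministic per seed.
#'
#' @param spec a `phantom_spec`.
#' @param label `"pCR"` or `"non-pCR"`.
#' @param seed integer seed.
#' @return list with `volume` (an `image_volume`) and `mask` (a `roi_mask`).
#' @export
generate_phantom <- function(spec = phantom_spec(), label = "non-pCR", seed = 1L) {
  label <- match.arg(label, PCR_LEVELS)
  d <- spec$grid_dim
  sp <- spec$spacing
  centre <- (d - 1) * sp / 2
  cx <- ((seq_len(d[1]) - 1) * sp[1] - centre[1]) / spec$semi_axes[1]
  cy <- ((seq_len(d[2]) - 1) * sp[2] - centre[2]) / spec$semi_axes[2]
  cz <- ((seq_len(d[3]) - 1) * sp[3] - centre[3]) / spec$semi_axes[3]
  r2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  mask_arr <- (r2 <= 1) + 0

  is_pcr <- label == "pCR"
  ell <- spec$corr_length * if (is_pcr) spec$delta_texture else 1
  sigma_vox <- ell / sp
  set.seed(seed)
  field <- gauss_smooth3d(array(stats::rnorm(prod(d)), d), sigma_vox)
  fsd <- stats::sd(field)
  if (fsd > 0) field <- field / fsd * spec$texture_sd
  mean_in <- spec$base_mean + if (is_pcr) spec$delta_mean else 0
  vox <- array(0.15 + stats::rnorm(prod(d), sd = spec$noise_sd), d)
  vox[mask_arr == 1] <- mean_in + field[mask_arr == 1]
  vox <- pmin(pmax(vox, 0), 1)
  list(volume = image_volume(array(vox, d), spacing = sp),
       mask = roi_mask(mask_arr, spacing = sp))
}

# per-class category proportions mirroring the published cohort table
default_clinical_proportions <- function() {
  list(
    figo_stage = list(pCR = c(IB = 3, `IIA-IIB` = 39, `IIIA-IIIC1` = 32) / 74,
                      `non-pCR` = c(IB = 4, `IIA-IIB` = 32, `IIIA-IIIC1` = 28) / 64),
    path_type = list(pCR = c(squamous = 73, adeno = 1, other = 0) / 74,
                     `non-pCR` = c(squamous = 59, adeno = 4, other = 1) / 64),
    scc_level = list(pCR = c(`<1.5` = 25, `1.5-5` = 16, `>5` = 11, unclear = 22) / 74,
                     `non-pCR` = c(`<1.5` = 13, `1.5-5` = 12, `>5` = 19, unclear = 20) / 64),
    lymph_node = list(pCR = c(negative = 50, positive = 24) / 74,
                      `non-pCR` = c(negative = 52, positive = 12) / 64),
    tumor_diameter = list(pCR = c(`<4` = 20, `>=4` = 54) / 74,
                          `non-pCR` = c(`<4` = 16, `>=4` = 48) / 64),
    rt_tech = list(pCR = c(`3DRT` = 54, IMRT = 20) / 74,
                   `non-pCR` = c(`3DRT` = 46, IMRT = 18) / 64)
  )
}

# draw n category values matching proportions up to rounding, shuffled
sample_categories <- function(props, n) {
  cnt <- diff(round(cumsum(c(0, props)) * n))
  cnt[length(cnt)] <- n - sum(cnt[-length(cnt)])
  sample(rep(names(props), times = cnt))
}

#' Generate a synthetic clinical table
#'
#' Draws per-class categorical variables whose marginals match the supplied
#' proportions up to rounding (defaults mirror the published cohort) and
#' ages from a clipped discretised normal centred near the published
#' medians (48 pCR / 47 non-pCR) within 25-65 years.
#'
#' @param n_pcr,n_nonpcr class sizes (defaults 74 and 64).
#' @param proportions nested list `variable -> class -> named proportions`;
#'   see `default_clinical_proportions` in the package source.
#' @param seed integer seed.
#' @return clinical data.frame (see [read_clinical_csv()] for the columns).
#' @export
generate_clinical_table <- function(n_pcr = 74L, n_nonpcr = 64L,
                                    proportions = default_clinical_proportions(),
                                    seed = 1L) {
  for (v in names(proportions)) for (cl in names(proportions[[v]])) {
    p <- proportions[[v]][[cl]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop_hybridpcr(sprintf("proportions for %s/%s must form a simplex", v, cl),
                     "hybridpcr_parameter_error")
  }
  set.seed(seed)
  one_class <- function(cl, n, age_centre) {
    df <- data.frame(
      age = pmin(pmax(round(stats::rnorm(n, age_centre, 9)), 25), 65)
    )
    for (v in names(proportions))
      df[[v]] <- sample_categories(proportions[[v]][[cl]], n)
    df$pcr_label <- cl
    df
  }
  out <- rbind(one_class("pCR", n_pcr, 48), one_class("non-pCR", n_nonpcr, 47))
  out <- cbind(patient_id = sprintf("P%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Generate paired class-conditional Gaussian feature matrices
#'
#' Fast path for classifier and cross-validation experiments: two feature
#' matrices (domain-vector and abstract-vector analogues) sharing labels
#' and sample order. A fraction of the columns of each matrix is
#' informative, with a mean shift of `effect` standard deviations for the
#' pCR class; the rest is pure noise. `effect = 0` gives two identically
#' distributed classes.
#'
#' @param n total samples (>= 4).
#' @param d_domain,d_abstract feature dimensions (defaults 114 and 95, the
#'   domain-plus-clinical and selected-abstract-plus-clinical widths).
#' @param effect class mean shift in sd units (>= 0).
#' @param informative_frac fraction of informative columns (default 0.2).
#' @param prevalence pCR fraction (default 74/138).
#' @param seed integer seed.
#' @return list with `domain`, `abstract` (matrices) and `labels` (factor).
#' @export
generate_feature_matrices <- function(n = 138L, d_domain = 114L, d_abstract = 95L,
                                      effect = 0, informative_frac = 0.2,
                                      prevalence = 74 / 138, seed = 1L) {
  if (n < 4L) stop_hybridpcr("n must be >= 4", "hybridpcr_parameter_error")
  if (effect < 0) stop_hybridpcr("effect must be >= 0", "hybridpcr_parameter_error")
  set.seed(seed)
  n_pcr <- round(n * prevalence)
  labels <- factor(sample(rep(PCR_LEVELS, c(n - n_pcr, n_pcr))),
                   levels = PCR_LEVELS)
  gen <- function(d, tag) {
    m <- matrix(stats::rnorm(n * d), n, d,
                dimnames = list(NULL, sprintf("%s_%03d", tag, seq_len(d))))
    n_inf <- round(informative_frac * d)
    if (n_inf > 0 && effect > 0)
      m[labels == "pCR", seq_len(n_inf)] <-
        m[labels == "pCR", seq_len(n_inf)] + effect
    m
  }
  list(domain = gen(d_domain, "dom"), abstract = gen(d_abstract, "abs"),
       labels = labels)
}

#' Materialise a full synthetic cohort on disk
#'
#' Writes one NIfTI volume/mask pair per patient plus `clinical.csv` in the
#' exact formats the pipeline reads.
#'
#' @param out_dir output directory (created if needed).
#' @param n_pcr,n_nonpcr class sizes.
#' @param spec a `phantom_spec`.
#' @param seed integer seed.
#' @return invisibly, the clinical data.frame (with file paths attached as
#'   columns `volume_file`, `mask_file`).
#' @export
simulate_cohort <- function(out_dir, n_pcr = 74L, n_nonpcr = 64L,
                            spec = phantom_spec(), seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  clin <- generate_clinical_table(n_pcr, n_nonpcr, seed = derive_seed(seed, 1))
  vol_files <- character(nrow(clin)); mask_files <- character(nrow(clin))
  for (i in seq_len(nrow(clin))) {
    ph <- generate_phantom(spec, label = clin$pcr_label[i],
                           seed = derive_seed(seed, 2, i))
    vol_files[i] <- file.path(out_dir, paste0(clin$patient_id[i], "_vol.nii.gz"))
    mask_files[i] <- file.path(out_dir, paste0(clin$patient_id[i], "_mask.nii.gz"))
    write_volume(ph$volume, vol_files[i])
    write_volume(ph$mask, mask_files[i])
  }
  clin$volume_file <- basename(vol_files)
  clin$mask_file <- basename(mask_files)
  utils::write.csv(clin, file.path(out_dir, "clinical.csv"), row.names = FALSE)
  invisible(clin)
}
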