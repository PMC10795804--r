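# Texture feature families computed from the gray-level matrices.
#
# Degenerate-value conventions (constant or single-voxel ROIs): GLCM
# correlation and MCC are reported as 1, IMC1/IMC2 as 0, NGTDM contrast /
# busyness / strength as 0 and coarseness as 1e6 when its denominator
# vanishes. These sentinels replace NaN so that feature vectors stay finite.

glcm_stats_single <- function(p) {
  g <- nrow(p)
  i <- matrix(seq_len(g), g, g)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(seq_len(g) * px); mu_y <- sum(seq_len(g) * py)
  sig_x <- sqrt(sum((seq_len(g) - mu_x)^2 * px))
  sig_y <- sqrt(sum((seq_len(g) - mu_y)^2 * py))
  # p_{x+y}(k), k = 2..2G and p_{x-y}(k), k = 0..G-1
  ksum <- 2:(2 * g); kdiff <- 0:(g - 1)
  p_sum <- vapply(ksum, function(k) sum(p[i + j == k]), 0)
  p_diff <- vapply(kdiff, function(k) sum(p[abs(i - j) == k]), 0)
  hx <- xlog2x_sum(px); hy <- xlog2x_sum(py)
  hxy <- xlog2x_sum(as.vector(p))
  pq <- outer(px, py)
  sel <- p > 0 & pq > 0
  hxy1 <- -sum(p[sel] * log2(pq[sel]))
  selq <- pq > 0
  hxy2 <- -sum(pq[selq] * log2(pq[selq]))
  da <- sum(kdiff * p_diff)

  corr <- if (sig_x > 0 && sig_y > 0)
    (sum(i * j * p) - mu_x * mu_y) / (sig_x * sig_y) else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy2 >= hxy) sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))) else 0

  mcc <- 1
  nz <- which(px > 0)
  if (length(nz) > 1) {
    pr <- p[nz, nz, drop = FALSE]
    a <- pr / px[nz]
    b <- sweep(pr, 2, py[nz], "/")
    qm <- a %*% t(b)
    ev <- sort(Re(eigen(qm, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(pmax(0, ev[2]))
  }

  c(
    Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - mu_x - mu_y)^4 * p),
    ClusterShade = sum((i + j - mu_x - mu_y)^3 * p),
    ClusterTendency = sum((i + j - mu_x - mu_y)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = xlog2x_sum(p_diff),
    DifferenceVariance = sum((kdiff - da)^2 * p_diff),
    Id = sum(p_diff / (1 + kdiff)),
    Idm = sum(p_diff / (1 + kdiff^2)),
    Idmn = sum(p_diff / (1 + (kdiff / g)^2)),
    Idn = sum(p_diff / (1 + kdiff / g)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = if (g > 1) sum(p_diff[-1] / kdiff[-1]^2) else 0,
    JointAverage = mu_x,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(ksum * p_sum),
    SumEntropy = xlog2x_sum(p_sum),
    SumSquares = sum((i - mu_x)^2 * p)
  )
}

#' Gray-level co-occurrence features
#'
#' Builds a symmetric, normalised co-occurrence matrix for each of the 13
#' unique 3D direction offsets at distance 1, computes the 24-feature GLCM
#' family per direction, and averages over the directions that contain at
#' least one voxel pair. A ROI with no valid pair in any direction (a single
#' voxel) falls back to the certain one-level matrix.
#'
#' @param q a `quantized_volume` (see [discretize()]).
#' @return named numeric vector of 24 features.
#' @export
glcm_features <- function(q) {
  dirs <- unique_offsets_13()
  mats <- lapply(seq_len(nrow(dirs)), function(k) glcm_matrix(q, dirs[k, ]))
  mats <- Filter(function(m) sum(m) > 0, mats)
  if (!length(mats)) {
    p <- matrix(0, q$n_levels, q$n_levels)
    lv1 <- q$levels[!is.na(q$levels)][1]
    p[lv1, lv1] <- 1
    mats <- list(p)
  }
  rowMeans(vapply(mats, glcm_stats_single, numeric(24)))
}

# shared "level/size" statistics for run-length-style matrices. mat[i, s]
# counts occurrences of gray level i with size/length/dependence s;
# np = ROI voxel count (for the percentage feature).
rl_family_stats <- function(mat, np, prefix_small, prefix_large, size_word) {
  nr <- sum(mat)
  g <- nrow(mat); smax <- ncol(mat)
  i <- seq_len(g); s <- seq_len(smax)
  ri <- rowSums(mat); rs <- colSums(mat)
  p <- mat / nr
  mu_i <- sum(i * rowSums(p)); mu_s <- sum(s * colSums(p))
  inv_i2 <- 1 / i^2; inv_s2 <- 1 / s^2
  out <- c(
    sum(t(mat) * inv_s2) / nr,                    # small emphasis
    sum(t(mat) * s^2) / nr,                       # large emphasis
    sum(ri^2) / nr,                               # gray-level non-uniformity
    sum(ri^2) / nr^2,                             # ... normalised
    sum(rs^2) / nr,                               # size non-uniformity
    sum(rs^2) / nr^2,                             # ... normalised
    nr / np,                                      # percentage
    sum(p * (i - mu_i)^2),                        # gray-level variance
    sum(t(p) * (s - mu_s)^2),                     # size variance
    xlog2x_sum(as.vector(p)),                     # entropy
    sum(mat * inv_i2) / nr,                       # low gray-level emphasis
    sum(mat * i^2) / nr,                          # high gray-level emphasis
    sum((mat * inv_i2) %*% diag(inv_s2, smax)) / nr,
    sum((mat * i^2) %*% diag(inv_s2, smax)) / nr,
    sum((mat * inv_i2) %*% diag(s^2, smax)) / nr,
    sum((mat * i^2) %*% diag(s^2, smax)) / nr
  )
  names(out) <- c(
    paste0(prefix_small, "Emphasis"), paste0(prefix_large, "Emphasis"),
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    paste0(size_word, "NonUniformity"), paste0(size_word, "NonUniformityNormalized"),
    paste0(size_word, "Percentage"), "GrayLevelVariance",
    paste0(size_word, "Variance"), paste0(size_word, "Entropy"),
    "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
    paste0(prefix_small, "LowGrayLevelEmphasis"),
    paste0(prefix_small, "HighGrayLevelEmphasis"),
    paste0(prefix_large, "LowGrayLevelEmphasis"),
    paste0(prefix_large, "HighGrayLevelEmphasis")
  )
  out
}

#' Gray-level run-length features
#'
#' Runs are maximal sequences of consecutive equal-level ROI voxels along a
#' direction; the 16-feature family is computed per direction over the 13
#' unique offsets and averaged.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glrlm_features <- function(q) {
  np <- sum(!is.na(q$levels))
  dirs <- unique_offsets_13()
  vals <- vapply(seq_len(nrow(dirs)), function(k) {
    rl_family_stats(glrlm_matrix(q, dirs[k, ]), np, "ShortRun", "LongRun", "Run")
  }, numeric(16))
  rowMeans(vals)
}

#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal gray level; the 16-feature
#' family mirrors the run-length statistics with zone size in place of run
#' length.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glszm_features <- function(q) {
  np <- sum(!is.na(q$levels))
  out <- rl_family_stats(glszm_matrix(q), np, "SmallArea", "LargeArea", "Zone")
  names(out)[names(out) == "ZoneNonUniformity"] <- "SizeZoneNonUniformity"
  names(out)[names(out) == "ZoneNonUniformityNormalized"] <-
    "SizeZoneNonUniformityNormalized"
  out
}

#' Gray-level dependence features
#'
#' The dependence of a voxel is 1 plus the number of its 26-neighbours in
#' the ROI whose gray level differs by at most `alpha` (default 0). The
#' 14-feature family drops the normalised gray-level non-uniformity and the
#' percentage entries of the run-length template (the dependence matrix
#' covers every ROI voxel exactly once, so the percentage is always 1).
#'
#' @inheritParams glcm_features
#' @param alpha dependence tolerance on level difference (default 0).
#' @return named numeric vector of 14 features.
#' @export
gldm_features <- function(q, alpha = 0) {
  np <- sum(!is.na(q$levels))
  full <- rl_family_stats(gldm_matrix(q, alpha), np,
                          "SmallDependence", "LargeDependence", "Dependence")
  keep <- setdiff(names(full), c("GrayLevelNonUniformityNormalized",
                                 "DependencePercentage"))
  full[keep]
}

#' Neighbourhood gray-tone difference features
#'
#' The classic 5-feature NGTDM family (coarseness, contrast, busyness,
#' complexity, strength) from the per-level occupancy `n_i` and summed
#' absolute deviation `s_i` of each voxel's level from its 26-neighbourhood
#' mean level.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 5 features.
#' @export
ngtdm_features <- function(q) {
  qq <- ngtdm_quantities(q)
  nv <- qq$n_total
  g <- length(qq$n)
  p <- qq$n / nv
  s <- qq$s
  present <- which(p > 0)
  ngp <- length(present)
  i <- seq_len(g)

  coars_den <- sum(p * s)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6

  contrast <- 0
  if (ngp > 1) {
    pij <- outer(p[present], p[present])
    dij2 <- outer(i[present], i[present], function(a, b) (a - b)^2)
    contrast <- (sum(pij * dij2) / (ngp * (ngp - 1))) * (sum(s) / nv)
  }

# denominator runs over ordered level pairs, as in the standard definition
  busy_den <- sum(abs(outer(i[present] * p[present], i[present] * p[present], "-")))
  busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0

  complexity <- 0
  strength <- 0
  if (ngp > 1) {
    ii <- i[present]
    pi_ <- p[present]; si_ <- s[present]
    adiff <- outer(ii, ii, function(a, b) abs(a - b))
    psum <- outer(pi_, pi_, "+")
    num <- outer(pi_ * si_, pi_ * si_, "+")
    complexity <- sum(adiff * num / psum) / nv
    strength_num <- sum(psum * adiff^2)
    strength <- if (sum(s) > 0) strength_num / sum(s) else 0
  }

  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}
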