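#' First-order intensity statistics of the tumor region
#'
#' The standard 18-feature first-order family describing the distribution of
#' voxel intensities inside the GTV. Energy-type features use raw
#' intensities; entropy and uniformity use the equal-width discretised
#' histogram (`n_bins` levels). Variance/deviation statistics are population
#' (divide by N). On a constant ROI, skewness and kurtosis are reported as 0
#' (documented degenerate-value convention) and uniformity as 1.
#'
#' Kurtosis is non-excess (a Gaussian scores about 3), matching the common
#' radiomics convention.
#'
#' @param vol an `image_volume`.
#' @param mask the paired non-empty `roi_mask`.
#' @param n_bins gray levels for the histogram-based entries (default 32).
#' @return named numeric vector of 18 features.
#' @export
first_order_features <- function(vol, mask, n_bins = 32L) {
  check_roi_nonempty(mask)
  x <- vol$voxels[mask$voxels > 0]
  n <- length(x)
  mu <- mean(x)
  cent <- x - mu
  var_p <- sum(cent^2) / n
  sd_p <- sqrt(var_p)
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  inter <- x[x >= q[1] & x <= q[5]]
  # histogram probabilities on the discretised levels
  qv <- discretize(vol, mask, n_bins = max(2L, n_bins))
  lev <- qv$levels[mask$voxels > 0]
  p <- tabulate(lev, nbins = qv$n_levels) / n
  c(
    Energy = sum(x^2),
    TotalEnergy = prod(vol$spacing) * sum(x^2),
    Entropy = xlog2x_sum(p),
    Minimum = min(x),
    P10 = q[1],
    P90 = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(cent)),
    RobustMeanAbsoluteDeviation =
      if (length(inter)) mean(abs(inter - mean(inter))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (sd_p > 0) mean(cent^3) / sd_p^3 else 0,
    Kurtosis = if (sd_p > 0) mean(cent^4) / sd_p^4 else 0,
    Variance = var_p,
    Uniformity = sum(p^2)
  )
}
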