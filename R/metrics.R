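# Classification metrics: confusion-count ratios, ROC and AUC.

#' Confusion counts with pCR as the positive class
#'
#' @param truth factor/character of true labels (`"non-pCR"` / `"pCR"`).
#' @param predicted factor/character of predicted labels.
#' @return named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  c(TP = sum(truth == "pCR" & predicted == "pCR"),
    FP = sum(truth == "non-pCR" & predicted == "pCR"),
    TN = sum(truth == "non-pCR" & predicted == "non-pCR"),
    FN = sum(truth == "pCR" & predicted == "non-pCR"))
}

#' Accuracy, sensitivity, specificity and precision from confusion counts
#'
#' Exact ratios: `TPR = TP / (TP + FN)`, `TNR = TN / (FP + TN)`,
#' `ACC = (TP + TN) / (TP + FN + FP + TN)`, `precision = TP / (FP + TP)`.
#' A metric whose denominator is zero is reported as `NA` with a warning.
#'
#' @param counts named vector with entries `TP`, `FP`, `TN`, `FN`.
#' @return named numeric vector `c(ACC, TPR, TNR, precision)`.
#' @export
metrics_from_counts <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  n <- tp + fp + tn + fn
  if (n == 0)
    stop_hybridpcr("all confusion counts are zero", "hybridpcr_parameter_error")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reporting NA", what))
      return(NA_real_)
    }
    num / den
  }
  c(ACC = (tp + tn) / n,
    TPR = ratio(tp, tp + fn, "TPR"),
    TNR = ratio(tn, fp + tn, "TNR"),
    precision = ratio(tp, fp + tp, "precision"))
}

#' Empirical ROC curve points
#'
#' Sweeps the decision threshold over the unique score values (scores are
#' probabilities or any monotone score for the positive class `"pCR"`) and
#' returns the ROC polygon from (0, 0) to (1, 1). Tied scores move along a
#' diagonal segment, so the trapezoidal area equals the tie-corrected
#' rank-statistic (Mann-Whitney) AUC.
#'
#' @param y_true factor/character of true labels.
#' @param scores numeric scores for the positive class.
#' @return data.frame with columns `fpr`, `tpr` (nondecreasing).
#' @export
roc_points <- function(y_true, scores) {
  y <- as.character(y_true) == "pCR"
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop_hybridpcr("ROC needs both classes present", "hybridpcr_parameter_error")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp_last <- c(ss[-1] != ss[-length(ss)], TRUE)
  tp <- cumsum(ys)[grp_last]
  fp <- cumsum(!ys)[grp_last]
  data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_points()]; numerically identical to the
#' normalised Mann-Whitney U statistic with ties counted one half.
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`.
#' @export
auc_from_scores <- function(y_true, scores) {
  rp <- roc_points(y_true, scores)
  sum(diff(rp$fpr) * (rp$tpr[-1] + rp$tpr[-nrow(rp)]) / 2)
}

#' Vertically average ROC curves on a fixed grid
#'
#' Interpolates each curve linearly at `n_grid` equally spaced
#' false-positive rates and averages the true-positive rates pointwise;
#' endpoints (0, 0) and (1, 1) are preserved.
#'
#' @param curves list of data.frames with columns `fpr`, `tpr`.
#' @param n_grid number of grid points (default 101).
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
aggregate_roc <- function(curves, n_grid = 101L) {
  if (!length(curves))
    stop_hybridpcr("need at least one ROC curve", "hybridpcr_parameter_error")
  grid <- seq(0, 1, length.out = n_grid)
  tprs <- vapply(curves, function(cv) {
    stats::approx(cv$fpr, cv$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(n_grid))
  data.frame(fpr = grid, tpr = rowMeans(tprs))
}
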