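# Repeated stratified cross-validation of the hybrid classifier.

#' Stratified fold assignment
#'
#' Assigns every sample to exactly one of `n_folds` test folds, balancing
#' both the per-class counts (difference at most 1 across folds within each
#' class) and the total fold sizes: remainders within a class go to the
#' folds with the smallest running totals (ties to the lowest fold index).
#' For a 74/64 two-class cohort and 5 folds this yields test-fold sizes
#' 28, 28, 28, 27, 27.
#'
#' @param labels class labels.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the within-class shuffles.
#' @return integer vector of fold ids (1..n_folds) per sample.
#' @export
make_stratified_folds <- function(labels, n_folds = 5L, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  fold <- integer(n)
  totals <- numeric(n_folds)
  set.seed(seed)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    n_c <- length(idx)
    base <- n_c %/% n_folds
    rem <- n_c %% n_folds
    cnt <- rep(base, n_folds)
    if (rem > 0) {
      extra <- order(totals, seq_len(n_folds))[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    pos <- 1L
    for (f in seq_len(n_folds)) {
      if (cnt[f] == 0) next
      fold[idx[pos:(pos + cnt[f] - 1L)]] <- f
      pos <- pos + cnt[f]
    }
    totals <- totals + cnt
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the hybrid classifier
#'
#' Runs `n_repeats` independent stratified `n_folds`-fold partitions (the
#' partition of repeat `r` depends only on `base_seed` and `r`). In every
#' fold, the full model - preprocessing, chi-square selection, member
#' training, inner validation split and ensemble weighting - is fitted on
#' the training fold only, then evaluated on the held-out test fold.
#' Metrics are AUC (trapezoidal, on the ensemble pCR probability) and the
#' confusion-count ratios ACC/TPR/TNR/precision from the argmax decision.
#'
#' @param features matrix or named list of matrices (see [hybrid_pcr()]).
#' @param labels `"non-pCR"` / `"pCR"` labels.
#' @param n_folds folds per repeat (default 5).
#' @param n_repeats repeats (default 20).
#' @param base_seed master seed; everything downstream derives from it.
#' @param member_auc also record each member's per-fold AUC (default FALSE).
#' @param ... passed to [hybrid_pcr()] (`classifiers`, `select_k`, `control`).
#' @return a `cv_report`: list with `folds` (per-fold metric data.frame),
#'   `per_repeat` (repeat means), `summary` (mean and sd over all fold
#'   evaluations and over repeat means), `mean_roc` (vertically averaged
#'   ROC on a 101-point grid), and `member_auc` if requested.
#' @export
run_repeated_cv <- function(features, labels, n_folds = 5L, n_repeats = 20L,
                            base_seed = 1L, member_auc = FALSE, ...) {
  if (is.matrix(features) || is.data.frame(features))
    features <- list(features = as.matrix(features))
  y <- as_pcr_factor(labels)
  if (min(table(y)) < n_folds)
    stop_hybridpcr("each class needs at least n_folds samples",
                   "hybridpcr_parameter_error")
  fold_rows <- list()
  curves <- list()
  member_rows <- list()
  member_names <- NULL
  for (r in seq_len(n_repeats)) {
    fold <- make_stratified_folds(y, n_folds, seed = derive_seed(base_seed, 101, r))
    for (f in seq_len(n_folds)) {
      test <- fold == f
      tr_feats <- lapply(features, function(m) m[!test, , drop = FALSE])
      te_feats <- lapply(features, function(m) m[test, , drop = FALSE])
      fit <- hybrid_pcr(tr_feats, y[!test],
                        seed = derive_seed(base_seed, 202, r, f), ...)
      pr <- predict(fit, te_feats, type = "both")
      counts <- confusion_counts(y[test], pr$class)
      mets <- suppressWarnings(metrics_from_counts(counts))
      auc <- auc_from_scores(y[test], pr$prob[, "pCR"])
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        repeat_id = r, fold = f, n_test = sum(test), AUC = auc,
        ACC = mets[["ACC"]], TPR = mets[["TPR"]], TNR = mets[["TNR"]],
        precision = mets[["precision"]])
      curves[[length(curves) + 1L]] <- roc_points(y[test], pr$prob[, "pCR"])
      if (member_auc) {
        if (is.null(member_names)) member_names <- names(fit$members)
        h <- predict_members(fit, te_feats)
        member_rows[[length(member_rows) + 1L]] <- vapply(
          seq_len(dim(h)[3]),
          function(i) auc_from_scores(y[test], h[, "pCR", i]), 0)
      }
    }
  }
  folds <- do.call(rbind, fold_rows)
  metric_cols <- c("AUC", "ACC", "TPR", "TNR", "precision")
  per_repeat <- stats::aggregate(folds[metric_cols],
                                 by = list(repeat_id = folds$repeat_id),
                                 FUN = mean, na.rm = TRUE)
  summ <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(folds[[m]], na.rm = TRUE), 0),
    sd_fold = vapply(metric_cols, function(m) stats::sd(folds[[m]], na.rm = TRUE), 0),
    sd_repeat = vapply(metric_cols, function(m) stats::sd(per_repeat[[m]]), 0)
  )
  rownames(summ) <- NULL
  out <- list(folds = folds, per_repeat = per_repeat, summary = summ,
              mean_roc = aggregate_roc(curves),
              n_folds = n_folds, n_repeats = n_repeats, base_seed = base_seed)
  if (member_auc) {
    ma <- do.call(rbind, member_rows)
    colnames(ma) <- member_names
    out$member_auc <- ma
  }
  class(out) <- "cv_report"
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Repeated stratified cross-validation: %d folds x %d repeats\n",
              x$n_folds, x$n_repeats))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %.3f +/- %.3f (fold-level sd; repeat-level %.3f)\n",
                s$metric[i], s$mean[i], s$sd_fold[i], s$sd_repeat[i]))
  invisible(x)
}

#' @export
plot.cv_report <- function(x, ...) {
  graphics::plot(x$mean_roc$fpr, x$mean_roc$tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "Mean ROC over repeated cross-validation", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
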