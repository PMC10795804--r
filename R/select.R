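#' Chi-square feature scores for a two-class problem
#'
#' Frequency-style chi-square relevance score for continuous nonnegative
#' features. Each feature is first min-max scaled to `[0, 1]` (columnwise,
#' on the data supplied — in cross-validation this must be the training
#' fold), then scored as `sum_c (O_c - E_c)^2 / E_c`, where `O_c` is the
#' feature's summed value within class `c` and `E_c = total * n_c / n` the
#' expectation under class independence. A feature constant across samples
#' scores 0.
#'
#' @param x numeric sample-by-feature matrix.
#' @param labels two-class factor/character vector of length `nrow(x)`.
#' @return list with `scores` (per-feature, >= 0) and `ranges` (the min-max
#'   scaling state, a 2 x p matrix), class `selection_scores`.
#' @export
chi_square_scores <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop_hybridpcr("chi-square scoring needs exactly two classes",
                   "hybridpcr_parameter_error")
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  rng <- hi - lo
  const <- rng <= 0
  rng[const] <- 1
  xs <- sweep(sweep(x, 2, lo), 2, rng, "/")
  n <- nrow(xs)
  cls <- levels(labels)
  n_c <- as.vector(table(labels))
  tot <- colSums(xs)
  scores <- numeric(ncol(xs))
  nonzero <- tot > 0
  if (any(nonzero)) {
    obs <- vapply(cls, function(cl) colSums(xs[labels == cl, , drop = FALSE]),
                  numeric(ncol(xs)))
    exp_ <- outer(tot, n_c / n)
    contrib <- (obs - exp_)^2 / exp_
    contrib[!nonzero, ] <- 0
    scores <- rowSums(contrib)
  }
  scores[const] <- 0
  names(scores) <- colnames(x)
  structure(list(scores = scores, ranges = rbind(min = lo, max = hi)),
            class = "selection_scores")
}

#' Indices of the top-k scored features
#'
#' @param scores a `selection_scores` object or a numeric score vector.
#' @param k number of features to keep (default 90); ties are broken by the
#'   lower index.
#' @return integer vector of `k` column indices, in decreasing score order.
#' @export
select_top_k <- function(scores, k = 90L) {
  s <- if (inherits(scores, "selection_scores")) scores$scores else scores
  if (k > length(s))
    stop_hybridpcr("k exceeds the number of features", "hybridpcr_parameter_error")
  if (k < 1L)
    stop_hybridpcr("k must be >= 1", "hybridpcr_parameter_error")
  order(-s, seq_along(s))[seq_len(k)]
}
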