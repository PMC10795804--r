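# The hybrid pCR classifier: base members (logistic regression, RBF
# support-vector machine with Platt-scaled probabilities, k-nearest
# neighbours, Gaussian naive Bayes), each trained per feature set, combined
# by accuracy-weighted soft voting:
#
#   H(x) = argmax_j  sum_i w_i h_ij(x)
#   w_i  = softmax(x_i),  x_i = logit(p_i)
#
# where h_ij(x) is member i's probability for class j and p_i its accuracy
# on an inner stratified validation hold-out of the training data (clipped
# away from 0 and 1 so the logit stays finite). Class order is fixed as
# (non-pCR, pCR) everywhere; exact argmax ties resolve to non-pCR.

PCR_LEVELS <- c("non-pCR", "pCR")

as_pcr_factor <- function(labels) {
  f <- factor(as.character(labels), levels = PCR_LEVELS)
  if (any(is.na(f)))
    stop_hybridpcr("labels must be 'non-pCR' or 'pCR'", "hybridpcr_parameter_error")
  f
}

#' Softmax-of-logit ensemble weights from validation accuracies
#'
#' Implements the adaptive weighting rule: accuracies are clipped to
#' `[eps, 1 - eps]`, mapped through the logit, and normalised by a softmax.
#' Weights are positive, sum to one, and are strictly increasing in the
#' clipped accuracy.
#'
#' @param p numeric vector of member validation accuracies in `[0, 1]`.
#' @param eps clipping margin keeping logits finite (default 1e-6).
#' @return an `ensemble_weights` object: list with `p` (clipped), `x`
#'   (logits) and `w` (softmax weights).
#' @export
compute_weights <- function(p, eps = 1e-6) {
  if (any(p < 0 | p > 1))
    stop_hybridpcr("accuracies must lie in [0, 1]", "hybridpcr_parameter_error")
  pc <- pmin(pmax(p, eps), 1 - eps)
  x <- stats::qlogis(pc)
  structure(list(p = pc, x = x, w = softmax(x)), class = "ensemble_weights")
}

#' @export
print.ensemble_weights <- function(x, ...) {
  cat("Ensemble weights (softmax of accuracy logits):\n")
  print(round(rbind(accuracy = x$p, weight = x$w), 4))
  invisible(x)
}

# stratified index split: TRUE = hold-out
stratified_holdout <- function(labels, fraction, seed) {
  labels <- as.factor(labels)
  hold <- logical(length(labels))
  set.seed(seed)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_h <- max(1L, round(fraction * length(idx)))
    hold[sample(idx, n_h)] <- TRUE
  }
  hold
}

# --- base members ------------------------------------------------------

fit_member <- function(type, x, y, control) {
  switch(type,
    lr = {
      # glmnet warns about very small classes on tiny folds; expected here
      fit <- withCallingHandlers(
        glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                       lambda = control$lr_lambda, standardize = FALSE),
        warning = function(w) {
          if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      list(type = "lr", fit = fit)
    },
    svm = {
      fit <- e1071::svm(x, y, kernel = "radial", cost = control$svm_cost,
                        gamma = control$svm_gamma %||% (1 / ncol(x)),
                        scale = FALSE)
      dv <- attr(stats::predict(fit, x, decision.values = TRUE),
                 "decision.values")[, 1]
      y01 <- as.numeric(y == PCR_LEVELS[2])
      platt <- suppressWarnings(
        stats::glm(y01 ~ dv, family = stats::binomial())
      )
      list(type = "svm", fit = fit, platt = stats::coef(platt))
    },
    knn = list(type = "knn", x = x, y = y, k = control$knn_k),
    nb = {
      fit <- e1071::naiveBayes(x, y)
      list(type = "nb", fit = fit)
    },
    stop_hybridpcr(paste("unknown classifier type:", type),
                   "hybridpcr_parameter_error")
  )
}

# probability matrix (n x 2), columns ordered (non-pCR, pCR)
predict_member_prob <- function(member, x) {
  p_pcr <- switch(member$type,
    lr = as.vector(stats::predict(member$fit, x, type = "response")),
    svm = {
      dv <- attr(stats::predict(member$fit, x, decision.values = TRUE),
                 "decision.values")[, 1]
      cf <- member$platt
      if (any(!is.finite(cf))) cf[!is.finite(cf)] <- 0
      stats::plogis(cf[1] + cf[2] * dv)
    },
    knn = {
      d2 <- outer(rowSums(x^2), rowSums(member$x^2), "+") -
        2 * x %*% t(member$x)
      apply(d2, 1, function(row) {
        nn <- order(row)[seq_len(min(member$k, length(row)))]
        mean(member$y[nn] == PCR_LEVELS[2])
      })
    },
    nb = stats::predict(member$fit, x, type = "raw")[, PCR_LEVELS[2]]
  )
  p_pcr <- pmin(pmax(p_pcr, 0), 1)
  cbind(`non-pCR` = 1 - p_pcr, pCR = p_pcr)
}

# --- per-feature-set preprocessing -------------------------------------

fit_preproc <- function(x, y, select_k, select_within = NULL) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  keep <- which(sds > 1e-12)
  if (!length(keep))
    stop_hybridpcr("feature set has no non-constant feature", "hybridpcr_parameter_error")
  xk <- x[, keep, drop = FALSE]
  sel <- seq_len(ncol(xk))
  if (!is.null(select_k)) {
    # columns eligible for selection; the rest are kept unconditionally
    elig <- if (is.null(select_within)) sel else {
      if (is.character(select_within)) which(colnames(xk) %in% select_within)
      else which(keep %in% select_within)
    }
    sc <- chi_square_scores(xk[, elig, drop = FALSE], y)
    top <- elig[select_top_k(sc, k = min(select_k, length(elig)))]
    sel <- sort(c(setdiff(sel, elig), top))
  }
  xs <- xk[, sel, drop = FALSE]
  list(keep = keep, sel = sel,
       center = colMeans(xs), scale = pmax(apply(xs, 2, stats::sd), 1e-12),
       p_in = ncol(x))
}

apply_preproc <- function(x, state) {
  x <- as.matrix(x)
  if (ncol(x) != state$p_in)
    stop_hybridpcr(sprintf("feature length mismatch: expected %d, got %d",
                           state$p_in, ncol(x)), "hybridpcr_shape_error")
  xs <- x[, state$keep, drop = FALSE][, state$sel, drop = FALSE]
  sweep(sweep(xs, 2, state$center), 2, state$scale, "/")
}

#' Control parameters for the hybrid classifier
#'
#' @param lr_lambda ridge penalty of the logistic member (default 0.01).
#' @param svm_cost,svm_gamma RBF support-vector parameters (defaults: cost 1,
#'   gamma `1/p`).
#' @param knn_k neighbours of the KNN member (default 5).
#' @param val_fraction inner validation hold-out fraction (default 0.2).
#' @param eps accuracy clipping margin for the weights (default 1e-6).
#' @param max_retries re-splits allowed if the inner hold-out loses a class.
#' @return list of control parameters.
#' @export
hybrid_control <- function(lr_lambda = 0.01, svm_cost = 1, svm_gamma = NULL,
                           knn_k = 5L, val_fraction = 0.2, eps = 1e-6,
                           max_retries = 10L) {
  list(lr_lambda = lr_lambda, svm_cost = svm_cost, svm_gamma = svm_gamma,
       knn_k = knn_k, val_fraction = val_fraction, eps = eps,
       max_retries = max_retries)
}

#' Fit the accuracy-weighted soft-voting hybrid classifier
#'
#' Trains one member per (feature set, classifier type) pair — with the
#' default two feature sets (domain and abstract vectors) and four types
#' this is the 8-member ensemble. Member validation accuracies come from an
#' inner stratified hold-out of the training data (default 20%); members
#' are then refit on the full training data and combined with
#' [compute_weights()]. All preprocessing (zero-variance removal, optional
#' chi-square top-k selection, standardisation) is fitted on the training
#' data only and stored in the model.
#'
#' @param features a numeric sample-by-feature matrix, or a named list of
#'   such matrices (one per feature set) sharing row order.
#' @param labels vector of `"non-pCR"` / `"pCR"` labels.
#' @param classifiers subset of `c("lr", "svm", "knn", "nb")`.
#' @param select_k `NULL` for no selection, a single count applied to every
#'   feature set, or a named vector giving the count per feature set (e.g.
#'   `c(abstract = 90)`).
#' @param select_within restricts chi-square selection to a column subset
#'   (character names or original indices); columns outside the subset are
#'   kept unconditionally. A list keyed by feature-set name, or a single
#'   vector applied to every set. Used to select within the abstract block
#'   of a concatenated abstract-plus-clinical matrix.
#' @param seed integer seed controlling the inner split (default 1).
#' @param control see [hybrid_control()].
#' @return an object of class `hybrid_pcr`.
#' @examples
#' sim <- generate_feature_matrices(n = 60, effect = 1.5, seed = 7)
#' fit <- hybrid_pcr(list(domain = sim$domain, abstract = sim$abstract),
#'                   sim$labels, seed = 7)
#' coef(fit)
#' @export
hybrid_pcr <- function(features, labels, classifiers = c("lr", "svm", "knn", "nb"),
                       select_k = NULL, select_within = NULL, seed = 1L,
                       control = hybrid_control()) {
  if (is.matrix(features) || is.data.frame(features))
    features <- list(features = as.matrix(features))
  if (is.null(names(features)))
    names(features) <- paste0("set", seq_along(features))
  features <- lapply(features, function(m) {
    m <- as.matrix(m)
    if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
    m
  })
  y <- as_pcr_factor(labels)
  n <- length(y)
  if (any(vapply(features, nrow, 0L) != n))
    stop_hybridpcr("all feature matrices must share the sample dimension",
                   "hybridpcr_parameter_error")
  if (nlevels(droplevels(y)) < 2L)
    stop_hybridpcr("both classes must be present for training",
                   "hybridpcr_parameter_error")
  classifiers <- match.arg(classifiers, c("lr", "svm", "knn", "nb"),
                           several.ok = TRUE)

  sel_for <- function(set_name) {
    if (is.null(select_k)) return(NULL)
    if (length(select_k) == 1L && is.null(names(select_k)))
      return(as.integer(select_k))
    if (set_name %in% names(select_k)) return(as.integer(select_k[[set_name]]))
    NULL
  }
  preproc <- lapply(names(features), function(nm)
    fit_preproc(features[[nm]], y, sel_for(nm),
                if (is.list(select_within)) select_within[[nm]] else select_within))
  names(preproc) <- names(features)
  xt <- lapply(names(features), function(nm)
    apply_preproc(features[[nm]], preproc[[nm]]))
  names(xt) <- names(features)

  # inner stratified hold-out for the validation accuracies
  hold <- NULL
  for (r in 0:control$max_retries) {
    cand <- stratified_holdout(y, control$val_fraction, derive_seed(seed, 17, r))
    if (nlevels(droplevels(y[!cand])) == 2L && nlevels(droplevels(y[cand])) == 2L) {
      hold <- cand; break
    }
  }
  if (is.null(hold))
    stop_hybridpcr("could not build an inner split containing both classes",
                   "hybridpcr_training_error")

  grid <- expand.grid(set = names(features), type = classifiers,
                      stringsAsFactors = FALSE)
  members <- vector("list", nrow(grid))
  p_val <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    xs <- xt[[grid$set[i]]]
    inner <- fit_member(grid$type[i], xs[!hold, , drop = FALSE], y[!hold], control)
    pv <- predict_member_prob(inner, xs[hold, , drop = FALSE])
    pred <- PCR_LEVELS[(pv[, 2] > pv[, 1]) + 1L]
    p_val[i] <- mean(pred == as.character(y[hold]))
    members[[i]] <- fit_member(grid$type[i], xs, y, control)
    members[[i]]$set <- grid$set[i]
  }
  names(members) <- paste(grid$set, grid$type, sep = ".")

  structure(list(
    members = members, member_grid = grid,
    weights = compute_weights(p_val, eps = control$eps),
    preproc = preproc, classes = PCR_LEVELS,
    n_train = n, seed = seed, control = control,
    call = match.call()
  ), class = "hybrid_pcr")
}

resolve_newdata <- function(object, newdata) {
  if (is.matrix(newdata) || is.data.frame(newdata))
    newdata <- stats::setNames(list(as.matrix(newdata)), names(object$preproc)[1])
  missing_sets <- setdiff(names(object$preproc), names(newdata))
  if (length(missing_sets))
    stop_hybridpcr(paste("newdata is missing feature set(s):",
                         paste(missing_sets, collapse = ", ")),
                   "hybridpcr_shape_error")
  lapply(stats::setNames(names(object$preproc), names(object$preproc)),
         function(nm) {
           m <- as.matrix(newdata[[nm]])
           if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
           apply_preproc(m, object$preproc[[nm]])
         })
}

#' Per-member class probabilities
#'
#' @param object a fitted `hybrid_pcr`.
#' @param newdata matrix or named list of matrices matching the training
#'   feature sets.
#' @return 3D array `(sample, class, member)`.
#' @export
predict_members <- function(object, newdata) {
  xt <- resolve_newdata(object, newdata)
  probs <- lapply(seq_along(object$members), function(i) {
    m <- object$members[[i]]
    predict_member_prob(m, xt[[m$set]])
  })
  arr <- array(unlist(probs),
               c(nrow(probs[[1]]), 2L, length(probs)),
               dimnames = list(NULL, PCR_LEVELS, names(object$members)))
  arr
}

#' Predict with the hybrid classifier
#'
#' Combines the member probability vectors with the stored softmax weights
#' (`F_j = sum_i w_i h_ij`) and predicts the argmax class; exact ties
#' resolve to `"non-pCR"`.
#'
#' @param object a fitted `hybrid_pcr`.
#' @param newdata matrix or named list of matrices.
#' @param type `"class"`, `"prob"` (the final probability matrix), or
#'   `"both"`.
#' @param ... unused.
#' @export
predict.hybrid_pcr <- function(object, newdata, type = c("class", "prob", "both"),
                               ...) {
  type <- match.arg(type)
  h <- predict_members(object, newdata)
  w <- object$weights$w
  f <- matrix(0, dim(h)[1], 2, dimnames = list(NULL, PCR_LEVELS))
  for (i in seq_along(w)) f <- f + w[i] * h[, , i]
  cls <- factor(PCR_LEVELS[(f[, 2] > f[, 1]) + 1L], levels = PCR_LEVELS)
  switch(type, class = cls, prob = f, both = list(class = cls, prob = f))
}

#' @export
coef.hybrid_pcr <- function(object, ...) {
  stats::setNames(object$weights$w, names(object$members))
}

#' @export
print.hybrid_pcr <- function(x, ...) {
  cat("Accuracy-weighted soft-voting hybrid pCR classifier\n")
  cat(sprintf("  %d members over feature set(s): %s\n", length(x$members),
              paste(names(x$preproc), collapse = ", ")))
  cat(sprintf("  trained on %d samples; classes (%s)\n", x$n_train,
              paste(x$classes, collapse = ", ")))
  cat("  weights:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
summary.hybrid_pcr <- function(object, ...) {
  df <- data.frame(
    member = names(object$members),
    feature_set = object$member_grid$set,
    classifier = object$member_grid$type,
    val_accuracy = object$weights$p,
    weight = object$weights$w
  )
  kept <- vapply(object$preproc, function(s) length(s$sel), 0L)
  out <- list(members = df, kept_features = kept, seed = object$seed)
  class(out) <- "summary.hybrid_pcr"
  out
}

#' @export
print.summary.hybrid_pcr <- function(x, ...) {
  cat("Hybrid pCR classifier summary\n\nMembers:\n")
  print(x$members, row.names = FALSE, digits = 4)
  cat("\nFeatures used per set:\n")
  print(x$kept_features)
  invisible(x)
}

#' @export
plot.hybrid_pcr <- function(x, ...) {
  graphics::barplot(coef(x), las = 2, ylab = "ensemble weight",
                    main = "Member weights", cex.names = 0.7, ...)
  invisible(x)
}
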