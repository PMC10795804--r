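# Multi-level pooled convolutional feature extractor.
#
# A five-stage VGG-style backbone: each stage is a block of 3x3
# (stride 1, zero-padded) convolutions with ReLU, followed by 2x2 max
# pooling. After every stage's pooling layer, a global average pooling tap
# captures the spatial mean of each channel; the five tapped vectors are
# concatenated stage 1 -> 5 into the abstract feature vector. With the
# default channel plan (64, 128, 256, 512, 512) this gives
# 64 + 128 + 256 + 512 + 512 = 1472 dimensions.
#
# Convolutions are evaluated as nine shifted matrix products (one per
# kernel tap), which maps the whole forward pass onto BLAS.

#' Backbone plan
#'
#' @param widths channel width per stage (default `c(64, 128, 256, 512, 512)`).
#' @param conv_counts number of 3x3 convolutions per stage (default
#'   `c(2, 2, 4, 4, 4)`, the VGG19 layout).
#' @param in_size input side length in pixels (default 224).
#' @return a `backbone_plan` list; `sum(widths)` is the abstract dimension.
#' @export
backbone_plan <- function(widths = c(64, 128, 256, 512, 512),
                          conv_counts = c(2, 2, 4, 4, 4),
                          in_size = 224L) {
  if (length(widths) != 5L || length(conv_counts) != 5L)
    stop_hybridpcr("a backbone plan has exactly 5 stages", "hybridpcr_parameter_error")
  if (any(widths < 1) || any(conv_counts < 1))
    stop_hybridpcr("stage widths and conv counts must be >= 1", "hybridpcr_parameter_error")
  structure(list(widths = as.integer(widths),
                 conv_counts = as.integer(conv_counts),
                 in_size = as.integer(in_size),
                 pooled_dims = as.integer(widths)),
            class = "backbone_plan")
}

#' Build the convolutional feature extractor
#'
#' Instantiates the five-stage backbone either from a serialized weights
#' file (an RDS holding the same nested list layout this function creates)
#' or from seeded random weights (He-scaled, zero bias). A missing weights
#' file falls back to seeded random weights with a warning. Outputs are
#' fully reproducible for a fixed seed.
#'
#' @param plan a `backbone_plan`.
#' @param weights path to a weights RDS file, or `NULL` for seeded random.
#' @param seed integer seed for random initialisation (default 1).
#' @return a `backbone` object usable with [extract_multilevel()].
#' @export
build_backbone <- function(plan = backbone_plan(), weights = NULL, seed = 1L) {
  stopifnot(inherits(plan, "backbone_plan"))
  if (!is.null(weights)) {
    if (file.exists(weights)) {
      w <- readRDS(weights)
      return(structure(list(plan = plan, stages = w$stages, head = w$head,
                            seed = NA_integer_), class = "backbone"))
    }
    warning("weights file not found; falling back to seeded random weights")
  }
  stages <- vector("list", 5L)
  c_in <- 3L
  for (s in 1:5) {
    n_out <- plan$widths[s]
    layers <- vector("list", plan$conv_counts[s])
    for (l in seq_len(plan$conv_counts[s])) {
      set.seed(derive_seed(seed, s, l))
      fan_in <- 9L * c_in
      # kernel stored as (9 * c_in) x c_out: rows ordered tap-major
      # (tap 1..9, within tap channel 1..c_in)
      layers[[l]] <- list(
        w = matrix(stats::rnorm(fan_in * n_out, sd = sqrt(2 / fan_in)),
                   fan_in, n_out),
        b = numeric(n_out),
        c_in = c_in, c_out = n_out
      )
      c_in <- n_out
    }
    stages[[s]] <- layers
  }
  structure(list(plan = plan, stages = stages, head = NULL, seed = seed),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("Five-stage convolutional backbone (input %dx%dx3)\n",
              x$plan$in_size, x$plan$in_size))
  cat(sprintf("  stage widths: %s; convs per stage: %s\n",
              paste(x$plan$widths, collapse = ", "),
              paste(x$plan$conv_counts, collapse = ", ")))
  cat(sprintf("  abstract feature dimension: %d\n", sum(x$plan$widths)))
  invisible(x)
}

# 3x3 same-padding convolution + ReLU on an (h*w) x c_in activation matrix.
# Implemented as a sum of nine shifted matrix products.
conv3x3_relu <- function(act, h, w, layer) {
  out <- matrix(rep(layer$b, each = h * w), h * w, layer$c_out)
  taps <- expand.grid(dr = -1:1, dc = -1:1)
  for (t in seq_len(9)) {
    dr <- taps$dr[t]; dc <- taps$dc[t]
    rows_src <- max(1, 1 + dr):min(h, h + dr)
    cols_src <- max(1, 1 + dc):min(w, w + dc)
    rows_dst <- rows_src - dr
    cols_dst <- cols_src - dc
    wt <- layer$w[((t - 1) * layer$c_in + 1):(t * layer$c_in), , drop = FALSE]
    src_idx <- as.vector(outer(rows_src, (cols_src - 1) * h, "+"))
    dst_idx <- as.vector(outer(rows_dst, (cols_dst - 1) * h, "+"))
    out[dst_idx, ] <- out[dst_idx, ] + act[src_idx, , drop = FALSE] %*% wt
  }
  out[out < 0] <- 0
  out
}

# 2x2 stride-2 max pool on an (h*w) x c activation matrix
maxpool2 <- function(act, h, w) {
  h2 <- h %/% 2L; w2 <- w %/% 2L
  r <- rep(seq_len(h2) * 2L - 1L, times = w2)
  c0 <- rep(seq_len(w2) * 2L - 2L, each = h2)
  i00 <- r + c0 * h
  m <- pmax(act[i00, , drop = FALSE], act[i00 + 1L, , drop = FALSE],
            act[i00 + h, , drop = FALSE], act[i00 + h + 1L, , drop = FALSE])
  m
}

# forward pass; returns per-stage pooled (GAP) vectors, and with
# keep_maps = TRUE also each stage's post-pool activation matrix
backbone_forward <- function(bb, pixels, keep_maps = FALSE) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  act <- matrix(pixels, h * w, dim(pixels)[3])
  pooled <- vector("list", 5L)
  maps <- if (keep_maps) vector("list", 5L) else NULL
  for (s in 1:5) {
    for (layer in bb$stages[[s]]) act <- conv3x3_relu(act, h, w, layer)
    if (h < 2L || w < 2L)
      stop_hybridpcr("input too small: spatial size collapsed before stage 5",
                     "hybridpcr_shape_error")
    act <- maxpool2(act, h, w)
    h <- h %/% 2L; w <- w %/% 2L
    pooled[[s]] <- colMeans(act)
    if (keep_maps) maps[[s]] <- list(h = h, w = w, act = act)
  }
  if (keep_maps) list(pooled = pooled, maps = maps) else pooled
}

#' Extract the multi-level pooled abstract feature vector
#'
#' Runs a preprocessed tumor slice through the backbone and concatenates
#' the global-average-pooled (per-channel spatial mean) activations tapped
#' after each of the five max-pooling layers, stage 1 to stage 5.
#'
#' @param slice a `preproc_slice` (or a `in_size x in_size x 3` array).
#' @param extractor a `backbone` from [build_backbone()].
#' @return named numeric vector of length `sum(plan$widths)` (1472 for the
#'   default plan), names tagged by stage (`s1_c001`, ..., `s5_c512`).
#' @export
extract_multilevel <- function(slice, extractor) {
  stopifnot(inherits(extractor, "backbone"))
  pixels <- if (inherits(slice, "preproc_slice")) slice$pixels else slice
  sz <- extractor$plan$in_size
  if (!identical(dim(pixels), c(sz, sz, 3L)) &&
      !identical(dim(pixels), as.integer(c(sz, sz, 3))))
    stop_hybridpcr(sprintf("input slice must be %dx%dx3", sz, sz),
                   "hybridpcr_shape_error")
  pooled <- backbone_forward(extractor, pixels)
  out <- unlist(pooled, use.names = FALSE)
  names(out) <- unlist(lapply(1:5, function(s)
    sprintf("s%d_c%03d", s, seq_len(extractor$plan$widths[s]))))
  out
}

#' Fine-tune the extractor on labelled slices
#'
#' Desk-scale transfer-learning stage: a logistic (softmax) head is trained
#' by full-batch gradient descent on the concatenated pooled features of the
#' labelled slices, and stored inside the extractor. The convolutional body
#' stays frozen, which keeps the stage cheap and exactly reproducible; with
#' `epochs = 0` the extractor is returned unchanged. This stage is optional:
#' the feature-extraction pipeline runs identically with or without it.
#'
#' @param extractor a `backbone`.
#' @param slices list of `preproc_slice` objects (or arrays).
#' @param labels factor/character vector with two classes, aligned with `slices`.
#' @param epochs gradient-descent epochs (default 10).
#' @param lr learning rate (default 0.05).
#' @return the extractor with an updated classification head and a
#'   `history` attribute of per-epoch training losses.
#' @export
fine_tune <- function(extractor, slices, labels, epochs = 10L, lr = 0.05) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop_hybridpcr("fine-tuning needs both classes present", "hybridpcr_training_error")
  if (epochs == 0L) return(extractor)
  feats <- t(vapply(slices, function(s) extract_multilevel(s, extractor),
                    numeric(sum(extractor$plan$widths))))
  mu <- colMeans(feats); sd <- apply(feats, 2, stats::sd); sd[sd < 1e-12] <- 1
  x <- sweep(sweep(feats, 2, mu), 2, sd, "/")
  y <- as.numeric(labels == levels(labels)[2])
  wts <- numeric(ncol(x)); b <- 0
  losses <- numeric(epochs)
  for (e in seq_len(epochs)) {
    eta <- as.vector(x %*% wts) + b
    p <- stats::plogis(eta)
    losses[e] <- -mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
    grad_w <- crossprod(x, p - y) / nrow(x)
    wts <- wts - lr * as.vector(grad_w)
    b <- b - lr * mean(p - y)
  }
  extractor$head <- list(w = wts, b = b, mu = mu, sd = sd,
                         classes = levels(labels))
  attr(extractor, "history") <- losses
  extractor
}

#' Predict slice labels with the fine-tuned head
#'
#' @param extractor a fine-tuned `backbone`.
#' @param slices list of slices.
#' @return factor of predicted labels.
#' @export
predict_slices <- function(extractor, slices) {
  if (is.null(extractor$head))
    stop_hybridpcr("extractor has no trained head; run fine_tune() first",
                   "hybridpcr_training_error")
  h <- extractor$head
  feats <- t(vapply(slices, function(s) extract_multilevel(s, extractor),
                    numeric(sum(extractor$plan$widths))))
  x <- sweep(sweep(feats, 2, h$mu), 2, h$sd, "/")
  p <- stats::plogis(as.vector(x %*% h$w) + h$b)
  factor(h$classes[(p >= 0.5) + 1L], levels = h$classes)
}
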