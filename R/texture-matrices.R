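# Gray-level matrix construction on the quantized ROI.
#
# All builders work on the `levels` array of a quantized_volume (integer
# levels 1..G inside the ROI, NA outside). Neighbourhoods are 3D at
# distance 1: 26 neighbours, of which 13 are unique up to sign.

all_offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  as.matrix(g)
}

# canonical half: dz > 0, or dz == 0 & dy > 0, or dz == dy == 0 & dx > 0
unique_offsets_13 <- function() {
  o <- all_offsets_26()
  keep <- o[, 3] > 0 | (o[, 3] == 0 & o[, 2] > 0) |
    (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0)
  o[keep, , drop = FALSE]
}

# index ranges of the overlap between a grid of size n and its copy shifted
# by d along one axis; both empty when |d| >= n
offset_ranges <- function(n, d) {
  if (d >= 0) list(a = seq_len(max(0L, n - d)), b = seq_len(max(0L, n - d)) + d)
  else list(a = seq_len(max(0L, n + d)) - d, b = seq_len(max(0L, n + d)))
}

# aligned sub-arrays of `arr` shifted by offset d: element k of $a sits at
# position p and element k of $b at position p + d
shifted_pair <- function(arr, d) {
  n <- dim(arr)
  rng <- lapply(1:3, function(a) offset_ranges(n[a], d[a]))
  if (any(vapply(rng, function(r) length(r$a) == 0L, TRUE)))
    return(list(a = integer(0), b = integer(0)))
  list(a = arr[rng[[1]]$a, rng[[2]]$a, rng[[3]]$a, drop = FALSE],
       b = arr[rng[[1]]$b, rng[[2]]$b, rng[[3]]$b, drop = FALSE])
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Counts pairs of ROI voxels at distance-1 offset `d`, symmetrises
#' (`C + t(C)`) and normalises to sum 1. Returns the `G x G` matrix, or a
#' zero matrix if the direction yields no valid pair.
#'
#' @param q a `quantized_volume`.
#' @param d integer length-3 offset.
#' @keywords internal
glcm_matrix <- function(q, d) {
  g <- q$n_levels
  sp <- shifted_pair(q$levels, d)
  a <- sp$a[!is.na(sp$a) & !is.na(sp$b)]
  b <- sp$b[!is.na(sp$a) & !is.na(sp$b)]
  cm <- matrix(0, g, g)
  if (length(a)) {
    counts <- tabulate((a - 1L) * g + b, nbins = g * g)
    cm <- matrix(counts, g, g, byrow = TRUE)
    cm <- cm + t(cm)
    cm <- cm / sum(cm)
  }
  cm
}

#' Gray-level run-length matrix for one direction
#'
#' Enumerates maximal runs of consecutive equal-level ROI voxels along
#' direction `d` (runs break at ROI borders). Returns the count matrix
#' `R[level, run length]`.
#' @keywords internal
glrlm_matrix <- function(q, d) {
  lv <- q$levels
  g <- q$n_levels
  idx <- which(!is.na(lv), arr.ind = TRUE)
  lev <- lv[!is.na(lv)]
  ax <- which(d != 0)[1]
  tpar <- idx[, ax] * sign(d[ax])
  key <- (idx[, 1] - tpar * d[1]) + (idx[, 2] - tpar * d[2]) * 1e3 +
    (idx[, 3] - tpar * d[3]) * 1e6
  ord <- order(key, tpar)
  key <- key[ord]; tpar <- tpar[ord]; lev_o <- lev[ord]
  newrun <- c(TRUE, diff(key) != 0 | diff(tpar) != 1 | diff(lev_o) != 0)
  run_id <- cumsum(newrun)
  run_len <- tabulate(run_id)
  run_lev <- lev_o[newrun]
  lmax <- max(run_len)
  matrix(tabulate((run_lev - 1L) * lmax + run_len, nbins = g * lmax),
         g, lmax, byrow = TRUE)
}

# connected-component labels (26-connectivity, equal level) via iterative
# minimum-label propagation on the grid
zone_labels <- function(lv) {
  d <- dim(lv)
  lab <- array(NA_real_, d)
  lab[!is.na(lv)] <- seq_len(sum(!is.na(lv)))
  offs <- all_offsets_26()
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(offs))) {
      dd <- offs[k, ]
      rng <- lapply(1:3, function(a) offset_ranges(d[a], dd[a]))
      if (any(vapply(rng, function(r) length(r$a) == 0L, TRUE))) next
      rng_a <- lapply(rng, `[[`, "a")
      rng_b <- lapply(rng, `[[`, "b")
      la <- lab[rng_a[[1]], rng_a[[2]], rng_a[[3]], drop = FALSE]
      lb <- lab[rng_b[[1]], rng_b[[2]], rng_b[[3]], drop = FALSE]
      va <- lv[rng_a[[1]], rng_a[[2]], rng_a[[3]], drop = FALSE]
      vb <- lv[rng_b[[1]], rng_b[[2]], rng_b[[3]], drop = FALSE]
      upd <- !is.na(va) & !is.na(vb) & va == vb & lb < la
      if (any(upd)) {
        la[upd] <- lb[upd]
        lab[rng_a[[1]], rng_a[[2]], rng_a[[3]]] <- la
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level inside the ROI.
#' Returns the count matrix `S[level, zone size]`.
#' @keywords internal
glszm_matrix <- function(q) {
  lv <- q$levels
  g <- q$n_levels
  lab <- zone_labels(lv)
  sel <- !is.na(lab)
  zl <- lab[sel]; lev <- lv[sel]
  sizes <- table(zl)
  zone_level <- lev[match(as.numeric(names(sizes)), zl)]
  sizes <- as.integer(sizes)
  smax <- max(sizes)
  matrix(tabulate((zone_level - 1L) * smax + sizes, nbins = g * smax),
         g, smax, byrow = TRUE)
}

#' Gray-level dependence matrix
#'
#' For every ROI voxel, the dependence is 1 (the voxel itself) plus the
#' number of its 26-neighbours inside the ROI whose level differs by at
#' most `alpha`. Returns the count matrix `D[level, dependence]`.
#' @keywords internal
gldm_matrix <- function(q, alpha = 0) {
  lv <- q$levels
  g <- q$n_levels
  dep <- array(0L, dim(lv))
  n <- dim(lv)
  for (k in seq_len(26)) {
    dd <- all_offsets_26()[k, ]
    sp <- shifted_pair(lv, dd)
    if (!length(sp$a)) next
    ok <- !is.na(sp$a) & !is.na(sp$b) & abs(sp$a - sp$b) <= alpha
    inc <- array(0L, dim(lv))
    rng_a <- lapply(1:3, function(a) offset_ranges(n[a], dd[a])$a)
    sub <- inc[rng_a[[1]], rng_a[[2]], rng_a[[3]], drop = FALSE]
    sub[ok] <- 1L
    inc[rng_a[[1]], rng_a[[2]], rng_a[[3]]] <- sub
    dep <- dep + inc
  }
  sel <- !is.na(lv)
  depv <- dep[sel] + 1L
  lev <- lv[sel]
  dmax <- max(depv)
  matrix(tabulate((lev - 1L) * dmax + depv, nbins = g * dmax),
         g, dmax, byrow = TRUE)
}

#' Neighbourhood gray-tone difference quantities
#'
#' Returns, per gray level i: `n_i` (voxels of level i with at least one
#' ROI neighbour), `s_i` (summed absolute difference between i and the mean
#' level of each such voxel's ROI neighbourhood), and the total voxel count.
#' @keywords internal
ngtdm_quantities <- function(q) {
  lv <- q$levels
  g <- q$n_levels
  nb_sum <- array(0, dim(lv))
  nb_cnt <- array(0L, dim(lv))
  offs <- all_offsets_26()
  n <- dim(lv)
  for (k in seq_len(26)) {
    dd <- offs[k, ]
    sp <- shifted_pair(lv, dd)
    if (!length(sp$a)) next
    ok <- !is.na(sp$a) & !is.na(sp$b)
    rng_a <- lapply(1:3, function(a) offset_ranges(n[a], dd[a])$a)
    s_sub <- nb_sum[rng_a[[1]], rng_a[[2]], rng_a[[3]], drop = FALSE]
    c_sub <- nb_cnt[rng_a[[1]], rng_a[[2]], rng_a[[3]], drop = FALSE]
    s_sub[ok] <- s_sub[ok] + sp$b[ok]
    c_sub[ok] <- c_sub[ok] + 1L
    nb_sum[rng_a[[1]], rng_a[[2]], rng_a[[3]]] <- s_sub
    nb_cnt[rng_a[[1]], rng_a[[2]], rng_a[[3]]] <- c_sub
  }
  sel <- !is.na(lv) & nb_cnt > 0L
  lev <- lv[sel]
  abar <- nb_sum[sel] / nb_cnt[sel]
  n_i <- tabulate(lev, nbins = g)
  s_i <- vapply(seq_len(g), function(i) sum(abs(i - abar)[lev == i]), 0)
  list(n = n_i, s = s_i, n_total = sum(n_i))
}
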