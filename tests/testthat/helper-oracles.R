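# Brute-force enumeration oracles for the gray-level texture families.
# Everything here is written as plain nested loops over voxels / matrix
# entries, independent of the vectorised implementation in the package.

offsets13 <- function() hybridpCR:::unique_offsets_13()
offsets26 <- function() hybridpCR:::all_offsets_26()

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# symmetrised, normalised co-occurrence matrix by explicit pair enumeration
oracle_glcm_matrix <- function(lv, g, off) {
  d <- dim(lv)
  cm <- matrix(0, g, g)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (is.na(a)) next
    q <- c(x, y, z) + off
    if (!in_grid(q, d)) next
    b <- lv[q[1], q[2], q[3]]
    if (is.na(b)) next
    cm[a, b] <- cm[a, b] + 1
    cm[b, a] <- cm[b, a] + 1
  }
  if (sum(cm) > 0) cm / sum(cm) else cm
}

oracle_glcm_stats <- function(p) {
  g <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- 0; mu_y <- 0
  for (i in 1:g) { mu_x <- mu_x + i * px[i]; mu_y <- mu_y + i * py[i] }
  sig_x <- sqrt(sum(sapply(1:g, function(i) (i - mu_x)^2 * px[i])))
  sig_y <- sqrt(sum(sapply(1:g, function(j) (j - mu_y)^2 * py[j])))
  psum <- rep(0, 2 * g); pdiff <- rep(0, g)
  for (i in 1:g) for (j in 1:g) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }
  ent <- function(v) { v <- v[v > 0]; if (!length(v)) 0 else -sum(v * log2(v)) }
  acc <- list(Autocorrelation = 0, ClusterProminence = 0, ClusterShade = 0,
              ClusterTendency = 0, Contrast = 0, JointEnergy = 0, SumSquares = 0)
  for (i in 1:g) for (j in 1:g) {
    acc$Autocorrelation <- acc$Autocorrelation + i * j * p[i, j]
    cc <- i + j - mu_x - mu_y
    acc$ClusterProminence <- acc$ClusterProminence + cc^4 * p[i, j]
    acc$ClusterShade <- acc$ClusterShade + cc^3 * p[i, j]
    acc$ClusterTendency <- acc$ClusterTendency + cc^2 * p[i, j]
    acc$Contrast <- acc$Contrast + (i - j)^2 * p[i, j]
    acc$JointEnergy <- acc$JointEnergy + p[i, j]^2
    acc$SumSquares <- acc$SumSquares + (i - mu_x)^2 * p[i, j]
  }
  hx <- ent(px); hy <- ent(py); hxy <- ent(as.vector(p))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:g) for (j in 1:g) {
    if (px[i] * py[j] > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(px[i] * py[j])
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
    }
  }
  kd <- 0:(g - 1)
  da <- sum(kd * pdiff)
  corr <- if (sig_x > 0 && sig_y > 0)
    (acc$Autocorrelation - mu_x * mu_y) / (sig_x * sig_y) else 1
  mcc <- 1
  nz <- which(px > 0)
  if (length(nz) > 1) {
    qm <- matrix(0, length(nz), length(nz))
    for (ii in seq_along(nz)) for (jj in seq_along(nz)) {
      s <- 0
      for (kk in seq_along(nz))
        s <- s + p[nz[ii], nz[kk]] * p[nz[jj], nz[kk]] / (px[nz[ii]] * py[nz[kk]])
      qm[ii, jj] <- s
    }
    ev <- sort(Re(eigen(qm, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(0, ev[2]))
  }
  c(Autocorrelation = acc$Autocorrelation,
    ClusterProminence = acc$ClusterProminence,
    ClusterShade = acc$ClusterShade,
    ClusterTendency = acc$ClusterTendency,
    Contrast = acc$Contrast,
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pdiff),
    DifferenceVariance = sum((kd - da)^2 * pdiff),
    Id = sum(pdiff / (1 + kd)),
    Idm = sum(pdiff / (1 + kd^2)),
    Idmn = sum(pdiff / (1 + (kd / g)^2)),
    Idn = sum(pdiff / (1 + kd / g)),
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = if (hxy2 >= hxy) sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))) else 0,
    InverseVariance = if (g > 1) sum(pdiff[-1] / kd[-1]^2) else 0,
    JointAverage = mu_x,
    JointEnergy = acc$JointEnergy,
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum((2:(2 * g)) * psum[-1]),
    SumEntropy = ent(psum),
    SumSquares = acc$SumSquares)
}

oracle_glcm_features <- function(lv, g) {
  dirs <- offsets13()
  mats <- list()
  for (k in seq_len(nrow(dirs))) {
    cm <- oracle_glcm_matrix(lv, g, dirs[k, ])
    if (sum(cm) > 0) mats[[length(mats) + 1]] <- cm
  }
  rowMeans(sapply(mats, oracle_glcm_stats))
}

# run enumeration by walking every line voxel-by-voxel
oracle_glrlm_matrix <- function(lv, g, off) {
  d <- dim(lv)
  counted <- array(FALSE, d)
  runs <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    p <- c(x, y, z)
    a <- lv[x, y, z]
    if (is.na(a) || counted[x, y, z]) next
    prev <- p - off
    if (in_grid(prev, d) && !is.na(lv[prev[1], prev[2], prev[3]]) &&
        lv[prev[1], prev[2], prev[3]] == a) next  # not a run start
    len <- 0; q <- p
    while (in_grid(q, d) && !is.na(lv[q[1], q[2], q[3]]) &&
           lv[q[1], q[2], q[3]] == a) {
      counted[q[1], q[2], q[3]] <- TRUE
      len <- len + 1
      q <- q + off
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  lmax <- max(sapply(runs, `[`, 2))
  rm_ <- matrix(0, g, lmax)
  for (r in runs) rm_[r[1], r[2]] <- rm_[r[1], r[2]] + 1
  rm_
}

oracle_rl_stats <- function(mat, np) {
  nr <- sum(mat)
  g <- nrow(mat); smax <- ncol(mat)
  p <- mat / nr
  mu_i <- 0; mu_s <- 0
  for (i in 1:g) for (s in 1:smax) {
    mu_i <- mu_i + i * p[i, s]; mu_s <- mu_s + s * p[i, s]
  }
  f <- rep(0, 16)
  ri <- rowSums(mat); rs <- colSums(mat)
  for (i in 1:g) for (s in 1:smax) {
    m <- mat[i, s]
    f[1] <- f[1] + m / s^2
    f[2] <- f[2] + m * s^2
    f[8] <- f[8] + p[i, s] * (i - mu_i)^2
    f[9] <- f[9] + p[i, s] * (s - mu_s)^2
    if (p[i, s] > 0) f[10] <- f[10] - p[i, s] * log2(p[i, s])
    f[11] <- f[11] + m / i^2
    f[12] <- f[12] + m * i^2
    f[13] <- f[13] + m / (i^2 * s^2)
    f[14] <- f[14] + m * i^2 / s^2
    f[15] <- f[15] + m * s^2 / i^2
    f[16] <- f[16] + m * i^2 * s^2
  }
  c(f[1] / nr, f[2] / nr, sum(ri^2) / nr, sum(ri^2) / nr^2,
    sum(rs^2) / nr, sum(rs^2) / nr^2, nr / np, f[8], f[9], f[10],
    f[11] / nr, f[12] / nr, f[13] / nr, f[14] / nr, f[15] / nr, f[16] / nr)
}

oracle_glrlm_features <- function(lv, g) {
  np <- sum(!is.na(lv))
  dirs <- offsets13()
  rowMeans(sapply(seq_len(nrow(dirs)), function(k)
    oracle_rl_stats(oracle_glrlm_matrix(lv, g, dirs[k, ]), np)))
}

# zones by recursive flood fill over the 26-neighbourhood
oracle_glszm_matrix <- function(lv, g) {
  d <- dim(lv)
  seen <- array(FALSE, d)
  offs <- offsets26()
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (is.na(lv[x, y, z]) || seen[x, y, z]) next
    a <- lv[x, y, z]
    stack <- list(c(x, y, z)); seen[x, y, z] <- TRUE; size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (in_grid(q, d) && !seen[q[1], q[2], q[3]] &&
            !is.na(lv[q[1], q[2], q[3]]) && lv[q[1], q[2], q[3]] == a) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  smax <- max(sapply(zones, `[`, 2))
  sm <- matrix(0, g, smax)
  for (zn in zones) sm[zn[1], zn[2]] <- sm[zn[1], zn[2]] + 1
  sm
}

oracle_glszm_features <- function(lv, g) {
  oracle_rl_stats(oracle_glszm_matrix(lv, g), sum(!is.na(lv)))
}

oracle_gldm_matrix <- function(lv, g, alpha = 0) {
  d <- dim(lv)
  offs <- offsets26()
  deps <- c()
  levs <- c()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (is.na(a)) next
    dep <- 1
    for (k in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[k, ]
      if (in_grid(q, d) && !is.na(lv[q[1], q[2], q[3]]) &&
          abs(lv[q[1], q[2], q[3]] - a) <= alpha) dep <- dep + 1
    }
    deps <- c(deps, dep); levs <- c(levs, a)
  }
  dm <- matrix(0, g, max(deps))
  for (i in seq_along(deps)) dm[levs[i], deps[i]] <- dm[levs[i], deps[i]] + 1
  dm
}

oracle_gldm_features <- function(lv, g, alpha = 0) {
  full <- oracle_rl_stats(oracle_gldm_matrix(lv, g, alpha), sum(!is.na(lv)))
  full[-c(4, 7)]  # drop normalised gray-level non-uniformity and percentage
}

oracle_ngtdm_features <- function(lv, g) {
  d <- dim(lv)
  offs <- offsets26()
  n_i <- rep(0, g); s_i <- rep(0, g); nv <- 0
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (is.na(a)) next
    vals <- c()
    for (k in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[k, ]
      if (in_grid(q, d) && !is.na(lv[q[1], q[2], q[3]]))
        vals <- c(vals, lv[q[1], q[2], q[3]])
    }
    if (!length(vals)) next
    nv <- nv + 1
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(vals))
  }
  p <- n_i / nv
  present <- which(p > 0)
  ngp <- length(present)
  coars <- if (sum(p * s_i) > 0) 1 / sum(p * s_i) else 1e6
  contrast <- 0; busy_den <- 0; complexity <- 0; strength_num <- 0
  for (i in present) for (j in present) {
    contrast <- contrast + p[i] * p[j] * (i - j)^2
    busy_den <- busy_den + abs(i * p[i] - j * p[j])
    complexity <- complexity + abs(i - j) * (p[i] * s_i[i] + p[j] * s_i[j]) / (p[i] + p[j])
    strength_num <- strength_num + (p[i] + p[j]) * (i - j)^2
  }
  contrast <- if (ngp > 1) contrast / (ngp * (ngp - 1)) * sum(s_i) / nv else 0
  c(Coarseness = coars,
    Contrast = contrast,
    Busyness = if (busy_den > 0) sum(p * s_i) / busy_den else 0,
    Complexity = if (ngp > 1) complexity / nv else 0,
    Strength = if (ngp > 1 && sum(s_i) > 0) strength_num / sum(s_i) else 0)
}

# random quantized ROI on a small grid: levels array with NA outside ROI
random_quantized_roi <- function(dim3, g, roi_frac = 0.8, seed = 1) {
  set.seed(seed)
  lv <- array(sample(1:g, prod(dim3), replace = TRUE), dim3)
  roi <- array(stats::runif(prod(dim3)) < roi_frac, dim3)
  if (!any(roi)) roi[1] <- TRUE
  lv[!roi] <- NA_integer_
  structure(list(levels = lv, n_levels = g, spacing = c(1, 1, 1)),
            class = "quantized_volume")
}

# pairwise-comparison AUC oracle (ties count one half)
oracle_auc <- function(y, s) {
  pos <- s[y == "pCR"]; neg <- s[y == "non-pCR"]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
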