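# Shape features of the GTV contour.
#
# Surface area and mesh volume are measured on a marching-tetrahedra
# triangulation of the 0.5 iso-surface of the mask occupancy field. The
# binary mask is first smoothed with a small Gaussian (sigma = 1 voxel
# per axis); this keeps the 0.5 level on the voxelised boundary but removes
# the staircase bias of meshing raw binary data, so that the measured area
# of digitised smooth objects converges to the true surface area with
# increasing resolution. Each inter-voxel cell is split into the six
# tetrahedra sharing its main diagonal; within a tetrahedron the field is
# linear, so the clipped volume and the planar iso-polygon have closed
# forms in the vertex values. Everything is accumulated per sign
# configuration, fully vectorised over cells.

# cube corner offsets, bit order (x, y, z)
.cube_corners <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
)
# six path tetrahedra sharing the c1-c7 main diagonal (1-based corner ids)
.tet_defs <- rbind(
  c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
  c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7)
)

# vectorised triangle area: p1, p2, p3 are n x 3 matrices
.tri_area_vec <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# vectorised |det| / 6 volume of tetrahedra given four n x 3 corner matrices
.tet_vol_vec <- function(p1, p2, p3, p4) {
  a <- p2 - p1; b <- p3 - p1; c <- p4 - p1
  abs(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

# cut point between vertex values fa (n-vector) and fb at level 0.5;
# va, vb are fixed 3-vectors (tet corner coordinates): returns n x 3
.cut_point <- function(fa, fb, va, vb) {
  t <- (0.5 - fa) / (fb - fa)
  outer(rep(1, length(fa)), va) + t * outer(rep(1, length(fa)), vb - va)
}

#' Surface area and mesh volume of the mask iso-surface
#'
#' @param mask a non-empty `roi_mask`.
#' @param smooth_sigma occupancy smoothing in voxels per axis (default 1;
#'   0 meshes the raw binary field, whose midpoint-cut staircase surface
#'   overestimates smooth-object areas).
#' @return list with `area` (mm^2) and `volume` (mm^3).
#' @export
mesh_surface_and_volume <- function(mask, smooth_sigma = 1) {
  sp <- mask$spacing
  m <- mask$voxels
  d <- dim(m)
  margin <- as.integer(1 + ceiling(3 * smooth_sigma))
  pd <- d + 2L * margin
  pad <- array(0, pd)
  pad[margin + seq_len(d[1]), margin + seq_len(d[2]), margin + seq_len(d[3])] <- m
  if (smooth_sigma > 0) pad <- gauss_smooth3d(pad, rep(smooth_sigma, 3))

  nc <- pd - 1L
  corner_vals <- lapply(seq_len(8), function(i) {
    dx <- .cube_corners[i, ]
    as.vector(pad[(1 + dx[1]):(nc[1] + dx[1]),
                  (1 + dx[2]):(nc[2] + dx[2]),
                  (1 + dx[3]):(nc[3] + dx[3])])
  })

  total_area <- 0; total_vol <- 0
  vtet <- prod(sp) / 6
  for (t in 1:6) {
    ids <- .tet_defs[t, ]
    verts <- .cube_corners[ids, , drop = FALSE] * matrix(sp, 4, 3, byrow = TRUE)
    f <- corner_vals[ids]
    ins <- lapply(f, function(v) v >= 0.5)
    cfg <- ins[[1]] + 2L * ins[[2]] + 4L * ins[[3]] + 8L * ins[[4]]
    # fully inside tetrahedra
    total_vol <- total_vol + vtet * sum(cfg == 15L)
    for (c_ in 1:14) {
      sel <- which(cfg == c_)
      if (!length(sel)) next
      b <- as.integer(intToBits(c_))[1:4]
      k <- sum(b)
      fi <- lapply(f, function(v) v[sel])
      if (k == 1L || k == 3L) {
        odd <- if (k == 1L) which(b == 1) else which(b == 0)
        rest <- setdiff(1:4, odd)
        tfrac <- lapply(rest, function(j)
          (0.5 - fi[[odd]]) / (fi[[j]] - fi[[odd]]))
        pts <- lapply(seq_len(3), function(jj)
          .cut_point(fi[[odd]], fi[[rest[jj]]], verts[odd, ], verts[rest[jj], ]))
        total_area <- total_area + sum(.tri_area_vec(pts[[1]], pts[[2]], pts[[3]]))
        frac <- tfrac[[1]] * tfrac[[2]] * tfrac[[3]]
        vol_odd <- vtet * frac
        total_vol <- total_vol + sum(if (k == 1L) vol_odd else vtet - vol_odd)
      } else {
        a_ <- which(b == 1); o_ <- which(b == 0)
        a1 <- a_[1]; a2 <- a_[2]; b1 <- o_[1]; b2 <- o_[2]
        p11 <- .cut_point(fi[[a1]], fi[[b1]], verts[a1, ], verts[b1, ])
        p12 <- .cut_point(fi[[a1]], fi[[b2]], verts[a1, ], verts[b2, ])
        p21 <- .cut_point(fi[[a2]], fi[[b1]], verts[a2, ], verts[b1, ])
        p22 <- .cut_point(fi[[a2]], fi[[b2]], verts[a2, ], verts[b2, ])
        total_area <- total_area + sum(.tri_area_vec(p11, p12, p22)) +
          sum(.tri_area_vec(p11, p22, p21))
        n_ <- length(sel)
        va1 <- outer(rep(1, n_), verts[a1, ])
        va2 <- outer(rep(1, n_), verts[a2, ])
        # clipped wedge = convex polyhedron (A1, P11, P12 | A2, P21, P22),
        # triangulated prism-fashion into three tetrahedra
        total_vol <- total_vol + sum(
          .tet_vol_vec(va1, p11, p12, va2) +
          .tet_vol_vec(p11, p12, va2, p21) +
          .tet_vol_vec(p12, va2, p21, p22))
      }
    }
  }
  list(area = total_area, volume = total_vol)
}

# physical (mm) coordinates of voxels selected by a logical 3D array
voxel_coords <- function(sel, spacing) {
  idx <- which(sel, arr.ind = TRUE)
  sweep(idx - 1, 2, spacing, "*")
}

max_pairwise <- function(pts) {
  if (nrow(pts) < 2) return(0)
  max(stats::dist(pts))
}

#' Shape features of the tumor mask
#'
#' The standard 14-feature 3D shape family: voxel-count and mesh volume,
#' surface area, surface/volume ratio, sphericity, maximum 3D diameter and
#' the three maximum in-plane diameters, principal-axis lengths, elongation
#' and flatness. Surface area and mesh volume come from
#' [mesh_surface_and_volume()]; principal axes from the eigenvalues of the
#' physical voxel-coordinate covariance (axis length `4 * sqrt(lambda)`).
#' Maximum 2D diameters are the largest pairwise surface-voxel distances in
#' each coordinate-plane projection. Degenerate ROIs (a single voxel, or
#' coplanar voxels) report axis ratios of 1.
#'
#' @param mask a non-empty `roi_mask`.
#' @return named numeric vector of 14 features (mm-based units).
#' @export
shape_features <- function(mask) {
  check_roi_nonempty(mask)
  sp <- mask$spacing
  m <- mask$voxels
  n_vox <- sum(m)
  sv <- mesh_surface_and_volume(mask)

  inroi <- m > 0
  pts <- voxel_coords(inroi, sp)
  # surface voxels: at least one absent 6-neighbour
  d <- dim(m)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  nb6 <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] + pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] +
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] + pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] +
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] + pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  surf <- inroi & (nb6 < 6L)
  spts <- voxel_coords(surf, sp)

  ev <- if (nrow(pts) > 1) {
    eigen(stats::cov(pts) * (nrow(pts) - 1) / nrow(pts), symmetric = TRUE,
          only.values = TRUE)$values
  } else c(0, 0, 0)
  ev <- pmax(ev, 0)

  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  c(
    MeshVolume = sv$volume,
    VoxelVolume = n_vox * prod(sp),
    SurfaceArea = sv$area,
    SurfaceVolumeRatio = sv$area / sv$volume,
    Sphericity = (36 * pi * sv$volume^2)^(1 / 3) / sv$area,
    Maximum3DDiameter = max_pairwise(spts),
    Maximum2DDiameterSlice = max_pairwise(spts[, c(1, 2), drop = FALSE]),
    Maximum2DDiameterColumn = max_pairwise(spts[, c(2, 3), drop = FALSE]),
    Maximum2DDiameterRow = max_pairwise(spts[, c(1, 3), drop = FALSE]),
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = elong,
    Flatness = flat
  )
}
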