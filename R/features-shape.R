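# 3-D shape descriptors of a binary mask. Voxel-based approximations (voxel
# counting for volume, face counting for surface area, PCA of voxel centres
# for axis lengths); no surface mesh is built.

shape_feature_names <- c(
  "Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
  "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "Maximum2DDiameterSlice",
  "Maximum3DDiameter", "MeshVolume", "MinorAxisLength", "Sphericity",
  "SurfaceArea", "SurfaceVolumeRatio", "VoxelVolume")

# boundary voxels: at least one 6-neighbour outside the mask (or grid edge)
boundary_voxels <- function(m) {
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  inner <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  inner & !nb
}

surface_area_faces <- function(m, sp) {
  d <- dim(m)
  area <- 0
  # exposed faces along each axis; face area = product of the two other spacings
  shift <- function(a, axis, by) {
    d <- dim(a)
    out <- array(FALSE, d)
    if (axis == 1) {
      if (by > 0) out[(1 + by):d[1], , ] <- a[1:(d[1] - by), , ] else out[1:(d[1] + by), , ] <- a[(1 - by):d[1], , ]
    } else if (axis == 2) {
      if (by > 0) out[, (1 + by):d[2], ] <- a[, 1:(d[2] - by), ] else out[, 1:(d[2] + by), ] <- a[, (1 - by):d[2], ]
    } else {
      if (by > 0) out[, , (1 + by):d[3]] <- a[, , 1:(d[3] - by)] else out[, , 1:(d[3] + by)] <- a[, , (1 - by):d[3]]
    }
    out
  }
  for (axis in 1:3) {
    fa <- prod(sp[-axis])
    area <- area + fa * (sum(m & !shift(m, axis, 1L)) + sum(m & !shift(m, axis, -1L)))
  }
  area
}

max_diam_subsample <- function(pts, cap = 2000L) {
  if (nrow(pts) < 2) return(0)
  if (nrow(pts) > cap) pts <- pts[seq(1, nrow(pts), length.out = cap), , drop = FALSE]
  cpp_max_pairwise_dist(pts)
}

compute_shape_features <- function(mask, spacing_mm) {
  m <- as_mask_array(mask)
  sp <- spacing_mm
  n <- sum(m)
  if (n < 1) stop("shape features: empty mask")
  vox_vol <- prod(sp)
  volume <- n * vox_vol
  sa <- surface_area_faces(m, sp)
  idx <- which(m, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, sp, `*`)  # voxel-centre world coordinates (mm)
  # PCA axis lengths (4 * sqrt(eigenvalue) convention)
  if (n > 1) {
    ev <- sort(eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev[ev < 0] <- 0
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  bidx <- which(boundary_voxels(m), arr.ind = TRUE)
  bpts <- sweep(bidx - 1, 2, sp, `*`)
  d3d <- max_diam_subsample(bpts)
  # largest in-plane diameters: slice = xy plane (per z), column = xz (per y),
  # row = yz (per x)
  plane_diam <- function(group_col, keep_cols) {
    if (nrow(bpts) < 2) return(0)
    best <- 0
    for (g in unique(bidx[, group_col])) {
      sel <- bidx[, group_col] == g
      if (sum(sel) >= 2)
        best <- max(best, max_diam_subsample(bpts[sel, keep_cols, drop = FALSE], 800L))
    }
    best
  }
  d2_slice <- plane_diam(3L, c(1L, 2L))
  d2_col <- plane_diam(2L, c(1L, 3L))
  d2_row <- plane_diam(1L, c(2L, 3L))
  spher <- if (sa > 0) (36 * pi * volume^2)^(1 / 3) / sa else 1
  vals <- c(elong, flat, least, major, d2_col, d2_row, d2_slice, d3d,
            volume, minor, spher, sa, if (volume > 0) sa / volume else 0, volume)
  stats::setNames(vals, shape_feature_names)
}
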