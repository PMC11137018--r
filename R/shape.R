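# Shape features of a binary VOI: mesh-based volume/area (marching
# tetrahedra on the 0.5 isosurface), principal-axis lengths, and maximum
# diameters.

vcross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# Mesh the 0.5 isosurface of the (optionally pre-smoothed) binary mask
# with marching tetrahedra (6 tetrahedra per cell around the main
# diagonal; crossings linearly interpolated) and return the enclosed
# volume and surface area in physical units.
#
# `smoothing` applies a separable [1,2,1]/4 kernel to the binary field
# before iso-extraction, which suppresses the staircase bias of the
# voxelized surface; it falls back to the raw binary field when the
# smoothed field has no interior voxel (very small masks).
mask_mesh_measures <- function(mask, spacing, smoothing = TRUE) {
  d <- dim(mask)
  f <- array(0, d + 4L)
  f[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- mask
  if (smoothing) {
    fs <- f
    for (a in 1:3) fs <- conv_axis(fs, c(1, 2, 1) / 4, a, mode = "reflect")
    if (any(fs > 0.5)) f <- fs
  }
  D <- dim(f)
  corner_off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  inside_sum <- array(0L, D - 1L)
  corner_vals <- vector("list", 8L)
  for (k in 1:8) {
    o <- corner_off[k, ]
    corner_vals[[k]] <- f[(1 + o[1]):(D[1] - 1 + o[1]),
                          (1 + o[2]):(D[2] - 1 + o[2]),
                          (1 + o[3]):(D[3] - 1 + o[3]), drop = FALSE]
    inside_sum <- inside_sum + (corner_vals[[k]] > 0.5)
  }
  mixed <- which(inside_sum > 0L & inside_sum < 8L)
  if (length(mixed) == 0) return(list(volume = 0, area = 0))
  Vm <- vapply(corner_vals, function(a) a[mixed], numeric(length(mixed)))
  if (is.null(dim(Vm))) Vm <- matrix(Vm, nrow = 1L)
  base <- which(array(TRUE, D - 1L), arr.ind = TRUE)[mixed, , drop = FALSE]
  tets <- list(c(0, 1, 2, 6), c(0, 2, 3, 6), c(0, 3, 7, 6),
               c(0, 7, 4, 6), c(0, 4, 5, 6), c(0, 5, 1, 6))
  sp <- spacing
  area <- 0; vol <- 0
  interp <- function(pA, pB, vA, vB) {
    t <- (0.5 - vA) / (vB - vA)
    pA + (pB - pA) * t
  }
  emit <- function(P1, P2, P3, ref) {
    nv <- vcross(P2 - P1, P3 - P1)
    cen <- (P1 + P2 + P3) / 3
    flip <- rowSums(nv * (cen - ref)) < 0
    if (any(flip)) {
      tmp <- P2[flip, , drop = FALSE]
      P2[flip, ] <- P3[flip, , drop = FALSE]
      P3[flip, ] <- tmp
    }
    nv <- vcross(P2 - P1, P3 - P1)
    area <<- area + 0.5 * sum(sqrt(rowSums(nv^2)))
    vol <<- vol + sum(rowSums(P1 * vcross(P2, P3))) / 6
  }
  for (tet in tets) {
    ci <- tet + 1L
    v <- Vm[, ci, drop = FALSE]
    pos <- lapply(ci, function(k)
      sweep(base, 2L, 1 - corner_off[k, ], "-") *
        matrix(sp, nrow(base), 3, byrow = TRUE))
    code <- (v[, 1] > 0.5) + 2L * (v[, 2] > 0.5) +
      4L * (v[, 3] > 0.5) + 8L * (v[, 4] > 0.5)
    single <- list(`1` = c(1, 2, 3, 4), `2` = c(2, 1, 3, 4),
                   `4` = c(3, 1, 2, 4), `8` = c(4, 1, 2, 3))
    triple <- list(`14` = c(1, 2, 3, 4), `13` = c(2, 1, 3, 4),
                   `11` = c(3, 1, 2, 4), `7` = c(4, 1, 2, 3))
    for (cs in names(single)) {               # one vertex inside
      sel <- code == as.integer(cs)
      if (!any(sel)) next
      a <- single[[cs]][1]; o <- single[[cs]][2:4]
      pA <- pos[[a]][sel, , drop = FALSE]
      vA <- v[sel, a]
      E <- lapply(o, function(b)
        interp(pA, pos[[b]][sel, , drop = FALSE], vA, v[sel, b]))
      emit(E[[1]], E[[2]], E[[3]], ref = pA)
    }
    for (cs in names(triple)) {               # one vertex outside
      sel <- code == as.integer(cs)
      if (!any(sel)) next
      a <- triple[[cs]][1]; o <- triple[[cs]][2:4]
      pA <- pos[[a]][sel, , drop = FALSE]
      vA <- v[sel, a]
      E <- lapply(o, function(b)
        interp(pos[[b]][sel, , drop = FALSE], pA, v[sel, b], vA))
      emit(E[[1]], E[[2]], E[[3]], ref = pos[[o[1]]][sel, , drop = FALSE])
    }
    pairs <- list(`3` = c(1, 2, 3, 4), `5` = c(1, 3, 2, 4),
                  `9` = c(1, 4, 2, 3), `6` = c(2, 3, 1, 4),
                  `10` = c(2, 4, 1, 3), `12` = c(3, 4, 1, 2))
    for (cs in names(pairs)) {                # two vertices inside
      sel <- code == as.integer(cs)
      if (!any(sel)) next
      pr <- pairs[[cs]]
      A <- pr[1]; B <- pr[2]; C <- pr[3]; Dv <- pr[4]
      pA <- pos[[A]][sel, , drop = FALSE]; pB <- pos[[B]][sel, , drop = FALSE]
      e1 <- interp(pA, pos[[C]][sel, , drop = FALSE], v[sel, A], v[sel, C])
      e2 <- interp(pA, pos[[Dv]][sel, , drop = FALSE], v[sel, A], v[sel, Dv])
      e3 <- interp(pB, pos[[C]][sel, , drop = FALSE], v[sel, B], v[sel, C])
      e4 <- interp(pB, pos[[Dv]][sel, , drop = FALSE], v[sel, B], v[sel, Dv])
      ref <- (pA + pB) / 2
      emit(e1, e2, e4, ref)
      emit(e1, e4, e3, ref)
    }
  }
  list(volume = abs(vol), area = area)
}

#' Sphericity from volume and surface area
#'
#' `(36 pi V^2)^(1/3) / A`; 1 for a perfect sphere, smaller for any other
#' shape.
#'
#' @param volume enclosed volume (mm^3).
#' @param area surface area (mm^2).
#' @export
sphericity_from_measurements <- function(volume, area) {
  if (area <= 0) stop("surface area must be positive")
  (36 * pi * volume^2)^(1 / 3) / area
}

#' Sphericity of a VOI mask
#'
#' Ratio of the surface area of a volume-matched sphere to the surface
#' area of a triangulated isosurface mesh of the mask.
#'
#' @param mask a [voi_mask()].
#' @param spacing optional spacing override (mm per axis).
#' @export
sphericity <- function(mask, spacing = mask$spacing) {
  m <- mask_mesh_measures(mask$values, spacing)
  if (m$area <= 0) stop("mask too small to mesh")
  sphericity_from_measurements(m$volume, m$area)
}

max_pairwise <- function(xy) {
  n <- nrow(xy)
  if (n < 2) return(0)
  best <- 0
  step <- 512L
  for (s in seq(1L, n, by = step)) {
    e <- min(n, s + step - 1L)
    d2 <- outer(rowSums(xy[s:e, , drop = FALSE]^2), rowSums(xy^2), "+") -
      2 * xy[s:e, , drop = FALSE] %*% t(xy)
    best <- max(best, max(d2))
  }
  sqrt(max(0, best))
}

boundary_voxels <- function(mask) {
  interior <- mask
  for (a in 1:3) {
    off <- c(0, 0, 0)
    for (s in c(-1, 1)) {
      off[a] <- s
      interior <- interior & shift_array(mask + 0, off) > 0
      off[a] <- 0
    }
  }
  which(mask & !interior, arr.ind = TRUE)
}

#' Shape features of a VOI mask
#'
#' The 14 standard 3D shape descriptors: mesh volume and voxel-count
#' volume, surface area, surface-to-volume ratio, sphericity, maximum 3D
#' diameter and per-plane maximum 2D diameters (largest boundary-voxel
#' distance within a shared slice/column/row), principal-axis lengths
#' (4 sqrt(lambda) of the physical-coordinate covariance eigenvalues),
#' elongation and flatness.
#'
#' @param mask a [voi_mask()].
#' @param spacing optional spacing override (mm per axis).
#' @return Named numeric vector of 14 features.
#' @export
shape_features <- function(mask, spacing = mask$spacing) {
  m <- mask$values
  nvox <- sum(m)
  mesh <- mask_mesh_measures(m, spacing)
  coords <- which(m, arr.ind = TRUE)
  phys <- sweep(coords, 2L, spacing, "*")
  if (nvox > 1) {
    ev <- sort(eigen(stats::cov(phys), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  bnd <- boundary_voxels(m)
  bphys <- sweep(bnd, 2L, spacing, "*")
  max2d <- function(plane_axis) {
    groups <- split(seq_len(nrow(bphys)), bnd[, plane_axis])
    max(0, vapply(groups, function(g)
      max_pairwise(bphys[g, -plane_axis, drop = FALSE]), 1))
  }
  c(MeshVolume = mesh$volume,
    VoxelVolume = nvox * prod(spacing),
    SurfaceArea = mesh$area,
    SurfaceVolumeRatio = if (mesh$volume > 0) mesh$area / mesh$volume else 0,
    Sphericity = if (mesh$area > 0)
      sphericity_from_measurements(mesh$volume, mesh$area) else 0,
    Maximum3DDiameter = max_pairwise(bphys),
    Maximum2DDiameterSlice = max2d(3L),
    Maximum2DDiameterColumn = max2d(2L),
    Maximum2DDiameterRow = max2d(1L),
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}

shape_names <- function()
  c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
    "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
    "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "MajorAxisLength",
    "MinorAxisLength", "LeastAxisLength", "Elongation", "Flatness")
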