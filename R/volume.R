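# 3D scalar volumes and binary regions of interest.
#
# A volume is stored as a plain R array with physical metadata: `spacing`
# (mm per axis, x/y/z = array dims 1/2/3) and `origin` (mm, physical
# coordinate of voxel [1,1,1]).  Physical coordinate of voxel i along axis
# a is origin[a] + (i - 1) * spacing[a].

#' Construct a 3D scalar volume
#'
#' @param values numeric 3D array of voxel intensities.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @param origin numeric length-3, physical position (mm) of the first voxel.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive finite values (mm)")
  if (any(!is.finite(values)))
    stop("voxel values must be finite")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "volume_image")
}

#' Construct a binary volume of interest mask
#'
#' @param values logical (or 0/1) 3D array; `TRUE` marks foreground voxels.
#' @param spacing,origin physical metadata, as in [volume_image()].
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("mask must be a 3D array")
  mode(values) <- "logical"
  if (!any(values))
    stop("mask has no foreground voxels")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voi_mask")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, spacing %s mm\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$values), collapse = "x"), sum(x$values),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

check_aligned <- function(image, mask) {
  if (!identical(dim(image$values), dim(mask$values)))
    stop("image and mask shapes differ: ",
         paste(dim(image$values), collapse = "x"), " vs ",
         paste(dim(mask$values), collapse = "x"))
  invisible(TRUE)
}

#' Resample an image and mask to a new voxel spacing
#'
#' Interpolates the image trilinearly (and the mask by nearest neighbour)
#' onto an axis-aligned grid at `target_spacing` covering the mask's
#' bounding box plus a one-voxel margin.  Image values outside the input
#' grid are edge-extended; mask values outside are background.
#'
#' @param image a [volume_image()].
#' @param mask a [voi_mask()] aligned with `image`.
#' @param target_spacing numeric length-3 (or scalar), mm per axis.
#' @return A list with resampled `image` and `mask`.
#' @export
resample_volume <- function(image, mask, target_spacing = c(2, 2, 2)) {
  check_aligned(image, mask)
  ts <- rep_len(as.numeric(target_spacing), 3L)
  if (any(ts <= 0)) stop("target spacing must be positive")
  dims <- dim(image$values)
  fg <- which(mask$values, arr.ind = TRUE)
  coords_out <- vector("list", 3L)
  for (a in 1:3) {
    pmin <- image$origin[a] + (min(fg[, a]) - 1) * image$spacing[a]
    pmax <- image$origin[a] + (max(fg[, a]) - 1) * image$spacing[a]
    coords_out[[a]] <- seq(pmin - ts[a], pmax + ts[a] * (1 + 1e-9), by = ts[a])
  }
  # continuous (1-based) input index of each output grid line, per axis
  ci <- lapply(1:3, function(a)
    (coords_out[[a]] - image$origin[a]) / image$spacing[a] + 1)
  i0 <- lapply(1:3, function(a) pmin(pmax(floor(ci[[a]]), 1), dims[a]))
  i1 <- lapply(1:3, function(a) pmin(i0[[a]] + 1, dims[a]))
  fr <- lapply(1:3, function(a) {
    f <- ci[[a]] - floor(ci[[a]])
    f[ci[[a]] < 1] <- 0
    f[ci[[a]] >= dims[a]] <- 0
    f
  })
  nout <- vapply(coords_out, length, 1L)
  out <- array(0, nout)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- if (dx) i1[[1]] else i0[[1]]
    iy <- if (dy) i1[[2]] else i0[[2]]
    iz <- if (dz) i1[[3]] else i0[[3]]
    wx <- if (dx) fr[[1]] else 1 - fr[[1]]
    wy <- if (dy) fr[[2]] else 1 - fr[[2]]
    wz <- if (dz) fr[[3]] else 1 - fr[[3]]
    w <- outer(outer(wx, wy), wz)
    out <- out + w * image$values[ix, iy, iz, drop = FALSE]
  }
  # nearest neighbour for the mask; outside the input grid -> background
  ni <- lapply(1:3, function(a) round(ci[[a]]))
  inside <- lapply(1:3, function(a) ni[[a]] >= 1 & ni[[a]] <= dims[a])
  nc <- lapply(1:3, function(a) pmin(pmax(ni[[a]], 1), dims[a]))
  mout <- mask$values[nc[[1]], nc[[2]], nc[[3]], drop = FALSE]
  mout <- mout & outer(outer(inside[[1]], inside[[2]]), inside[[3]])
  if (!any(mout))
    stop("mask is empty after resampling")
  new_origin <- vapply(coords_out, `[`, numeric(1), 1L)
  list(image = volume_image(out, ts, new_origin),
       mask = voi_mask(mout, ts, new_origin))
}

#' Discretize masked intensities into fixed-width gray-level bins
#'
#' Gray level of a foreground voxel with intensity x is
#' `floor((x - min) / bin_width) + 1`, where `min` is the masked minimum
#' (min-anchored fixed bin width), so levels are invariant to adding a
#' global intensity constant.
#'
#' @param image a [volume_image()].
#' @param mask aligned [voi_mask()].
#' @param bin_width positive bin width in intensity units (default 25).
#' @return An object of class `discretized_voi` with integer `levels`
#'   (`NA` outside the mask), the logical `mask` array, the level count
#'   `n_levels` and the `bin_width` used.
#' @export
discretize <- function(image, mask, bin_width = 25) {
  check_aligned(image, mask)
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("'bin_width' must be a positive number")
  m <- mask$values
  v <- image$values[m]
  lev <- as.integer(floor((v - min(v)) / bin_width)) + 1L
  levels <- array(NA_integer_, dim(m))
  levels[m] <- lev
  structure(list(levels = levels, mask = m, n_levels = max(lev),
                 bin_width = bin_width, spacing = image$spacing),
            class = "discretized_voi")
}

#' @export
print.discretized_voi <- function(x, ...) {
  cat(sprintf("<discretized_voi> %d foreground voxels, %d gray levels (bin width %g)\n",
              sum(x$mask), x$n_levels, x$bin_width))
  invisible(x)
}

#' Read a volume (or mask) from a NIfTI file
#'
#' Voxel spacing is taken from the header `pixdim`; the origin is set to
#' zero (only relative geometry is used downstream).
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param mask logical; read as a binary [voi_mask()] (values > 0.5).
#' @export
read_volume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), utils::head(dim(img), 3))
  if (mask) voi_mask(arr > 0.5, sp) else volume_image(arr, sp)
}

#' Write a volume or mask to a NIfTI file
#'
#' @param x a [volume_image()] or [voi_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(x, path) {
  vals <- if (inherits(x, "voi_mask")) x$values + 0L else x$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
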