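# Separable image filters: undecimated wavelet band decomposition and
# Laplacian-of-Gaussian, both built on a 1D convolution applied along one
# array axis at a time.

# Convolve along one axis.  `k` is the kernel, `center` its 1-based center
# tap; boundary handling is "reflect" (half-sample symmetric) or
# "periodic" (circular).  Output has the shape of the input.
conv_axis <- function(a, k, axis, mode = c("reflect", "periodic"),
                      center = (length(k) + 1L) %/% 2L) {
  mode <- match.arg(mode)
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(a, perm)
  d <- dim(x)
  n <- d[1L]
  xm <- matrix(x, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(xm))
  for (t in seq_along(k)) {
    idx <- seq_len(n) - (t - center)      # y[i] = sum_t k[t] x[i - (t-center)]
    if (mode == "periodic") {
      idx <- ((idx - 1L) %% n) + 1L
    } else {
      # symmetric reflection about half-sample boundaries: ...321|123...
      idx <- ((idx - 1L) %% (2L * n))
      idx <- ifelse(idx >= n, 2L * n - 1L - idx, idx) + 1L
    }
    out <- out + k[t] * xm[idx, , drop = FALSE]
  }
  aperm(array(out, d), order(perm))
}

# Orthonormal decomposition filter pairs (low, high).  Taps follow the
# usual quadrature-mirror convention g[n] = (-1)^n h[L-1-n].
wavelet_filters <- function(family = c("coif1", "haar")) {
  family <- match.arg(family)
  lo <- switch(family,
    coif1 = c(-0.0156557281357919, -0.0727326195125264, 0.3848648468648578,
              0.8525720202116004, 0.3378976624574818, -0.0727326195125264),
    haar = c(1, 1) / sqrt(2))
  n <- seq_along(lo) - 1L
  hi <- (-1)^n * rev(lo)
  list(lo = lo, hi = hi)
}

#' Undecimated single-level 3D wavelet band decomposition
#'
#' Applies one pass of an orthonormal low-pass (`L`) or high-pass (`H`)
#' filter along each axis, for all 8 combinations, with circular boundary
#' handling and no downsampling, so every band has the shape of the input.
#' Band labels give the filter per axis in array-axis order: the first
#' letter of e.g. `"LHH"` is the filter applied along axis 1 (x), the
#' second along axis 2 (y), the third along axis 3 (z).
#'
#' With an orthonormal filter pair the decomposition conserves energy up
#' to the per-axis gain of 2: summed over the 8 bands, the squared norm is
#' 8 times that of the input.
#'
#' @param image a [volume_image()], at least as wide as the filter along
#'   every axis.
#' @param family wavelet family; `"coif1"` (default) or `"haar"`.
#' @return Named list of 8 [volume_image()] bands
#'   (`LLL`, `LLH`, ..., `HHH`).
#' @export
wavelet_bands <- function(image, family = "coif1") {
  f <- wavelet_filters(family)
  if (any(dim(image$values) < length(f$lo)))
    stop("image smaller than the wavelet filter (", length(f$lo),
         " taps) along some axis")
  labels <- apply(expand.grid(c("L", "H"), c("L", "H"), c("L", "H")),
                  1L, paste0, collapse = "")
  out <- vector("list", 8L)
  names(out) <- labels
  for (lab in labels) {
    v <- image$values
    for (a in 1:3) {
      k <- if (substr(lab, a, a) == "L") f$lo else f$hi
      v <- conv_axis(v, k, a, mode = "periodic")
    }
    out[[lab]] <- volume_image(v, image$spacing, image$origin)
  }
  out
}

#' Laplacian-of-Gaussian filter in physical units
#'
#' Convolves the image with a separable Laplacian-of-Gaussian, `sigma`
#' given in mm and converted to voxels through the spacing of each axis.
#' The 1D second-derivative kernel is calibrated so that its response to
#' a quadratic ramp equals the true second derivative and its DC response
#' is exactly zero (a constant image maps to zero).  Boundaries are
#' handled by symmetric reflection.
#'
#' @param image a [volume_image()].
#' @param sigma Gaussian scale in mm (> 0).
#' @return A [volume_image()] of the filter response.
#' @export
log_filter <- function(image, sigma = 3) {
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be positive")
  kerns <- lapply(1:3, function(a) {
    h <- image$spacing[a]
    sv <- sigma / h
    r <- max(2L, ceiling(4 * sv))
    x <- (-r:r) * h
    g <- exp(-x^2 / (2 * sigma^2))
    g <- g / sum(g)
    k2 <- g * (x^2 - sigma^2) / sigma^4
    k2 <- k2 - mean(k2)                    # zero DC response
    k2 / sum(k2 * x^2 / 2)                 # unit response to x^2/2
  })
  gauss <- lapply(1:3, function(a) {
    h <- image$spacing[a]
    r <- max(2L, ceiling(4 * sigma / h))
    g <- exp(-((-r:r) * h)^2 / (2 * sigma^2))
    g / sum(g)
  })
  acc <- array(0, dim(image$values))
  for (a in 1:3) {
    v <- image$values
    for (b in 1:3) {
      k <- if (b == a) kerns[[b]] else gauss[[b]]
      v <- conv_axis(v, k, b, mode = "reflect")
    }
    acc <- acc + v
  }
  volume_image(acc, image$spacing, image$origin)
}
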