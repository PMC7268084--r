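#' 3D scalar map with an in-brain mask
#'
#' The common carrier for gray/white matter maps and for derived ReHo and
#' ALFF maps. Values must be finite inside the mask; the mask must be
#' non-empty.
#'
#' @param data 3D numeric array.
#' @param mask 3D logical array of the same shape; `TRUE` marks in-brain
#'   voxels. Defaults to all voxels.
#' @param voxel_size numeric length-3, voxel edges in mm.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, mask = NULL,
                         voxel_size = c(3, 3, 3)) {
  if (length(dim(data)) != 3L) stop("voxel_volume: data must be 3D")
  if (is.null(mask)) mask <- array(TRUE, dim(data))
  if (!identical(dim(mask), dim(data)))
    stop("voxel_volume: mask shape differs from data shape")
  if (!any(mask)) stop("voxel_volume: mask is empty")
  if (any(!is.finite(data[mask])))
    stop("voxel_volume: non-finite values inside mask")
  structure(list(data = data, mask = array(as.logical(mask), dim(mask)),
                 voxel_size = as.double(voxel_size)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s grid, %d in-mask voxels, voxel %s mm\n",
              paste(dim(x$data), collapse = "x"), sum(x$mask),
              paste(x$voxel_size, collapse = "x")))
  invisible(x)
}

# 1D Gaussian kernel, sigma in voxels, truncated at 4 sigma, unit sum.
gauss_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Convolve a 3D array along one axis with zero padding (kernel centered).
conv_axis <- function(a, k, axis) {
  if (length(k) == 1L) return(a * k)
  d <- dim(a)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  r <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow = d[axis], ncol = ncol(m))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(d[axis]) + off
    ok <- src >= 1L & src <= d[axis]
    out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
  }
  ap2 <- array(out, dim(ap))
  aperm(ap2, order(perm))
}

#' Gaussian spatial smoothing of a volume
#'
#' Separable Gaussian smoothing with kernel width given as full width at half
#' maximum in mm; per-axis sigma is `fwhm / (2 sqrt(2 ln 2))` divided by the
#' voxel size. Boundaries are handled by renormalization (the smoothed field
#' is divided by the smoothed all-ones field), so constant volumes are exact
#' fixed points. `fwhm_mm = 0` is the identity.
#'
#' @param v a [voxel_volume()].
#' @param fwhm_mm kernel full width at half maximum in mm (>= 0).
#' @return A smoothed `voxel_volume` with the same mask.
#' @export
smooth_volume <- function(v, fwhm_mm) {
  if (!inherits(v, "voxel_volume")) stop("smooth_volume: need voxel_volume")
  if (fwhm_mm < 0) stop("smooth_volume: fwhm_mm must be >= 0")
  if (any(v$voxel_size <= 0))
    stop("smooth_volume: voxel sizes must be positive")
  if (fwhm_mm == 0) return(v)
  sigmas <- fwhm_mm / (2 * sqrt(2 * log(2))) / v$voxel_size
  num <- v$data
  den <- array(1, dim(v$data))
  for (ax in 1:3) {
    k <- gauss_kernel_1d(sigmas[ax])
    num <- conv_axis(num, k, ax)
    den <- conv_axis(den, k, ax)
  }
  voxel_volume(num / den, v$mask, v$voxel_size)
}

#' Flatten the in-mask voxels of a volume to a feature vector
#'
#' Voxels are emitted in R's native column-major raster order (first axis
#' fastest), restricted to the mask, so vectors from subjects sharing a mask
#' are aligned feature-for-feature.
#'
#' @param v a [voxel_volume()].
#' @return Numeric vector of length `sum(v$mask)`.
#' @export
voxel_features <- function(v) {
  if (!inherits(v, "voxel_volume")) stop("voxel_features: need voxel_volume")
  as.double(v$data[v$mask])
}
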