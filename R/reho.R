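#' Regional homogeneity (ReHo) map
#'
#' Kendall's coefficient of concordance `W` between each in-mask voxel's
#' time series and those of its (up to) 26 nearest in-mask neighbours,
#' computed on the kept frames of a cleaned series:
#' `W = 12 * sum_t (R_t - K(n+1)/2)^2 / (K^2 (n^3 - n))` where `R_t` is the
#' rank sum over the `K` series at time `t`. Border voxels use whatever
#' neighbours fall inside the mask, with `K` adjusted. Ties get average
#' ranks; no tie correction is applied (ties have measure zero for
#' continuous data). With `normalize = TRUE` the map is divided by its
#' in-mask mean, so the emitted map has in-mask mean exactly 1.
#'
#' @param b a cleaned [bold_series()].
#' @param normalize divide by the in-mask (whole-brain) mean (default
#'   `TRUE`).
#' @param nbr optional precomputed neighbour index from
#'   [neighbor_index()] (cached by callers that process many subjects on
#'   one mask).
#' @return A [voxel_volume()] ReHo map.
#' @export
reho_map <- function(b, normalize = TRUE, nbr = NULL) {
  if (!inherits(b, "bold_series")) stop("reho_map: need a bold_series")
  X <- bold_matrix(b)
  if (is.null(nbr)) nbr <- neighbor_index(b$mask)
  W <- reho_core(X, nbr, normalize)
  vol <- array(0, dim(b$mask))
  vol[b$mask] <- W
  voxel_volume(vol, b$mask)
}

reho_core <- function(X, nbr, normalize = TRUE) {
  if (nrow(X) < 2) stop("reho_map: need at least 2 timepoints")
  W <- as.vector(cpp_reho(X, nbr))
  if (normalize) W <- W / mean(W)
  W
}

#' 26-neighbourhood index of an in-mask voxel grid
#'
#' `V x 27` matrix of 0-based in-mask column indices (self plus up to 26
#' neighbours), `-1`-padded, for the column-major in-mask voxel ordering
#' used throughout the package. Computed once per mask and reusable across
#' subjects.
#'
#' @param mask 3D logical array.
#' @return Integer matrix consumed by [reho_map()].
#' @export
neighbor_index <- function(mask) {
  d <- dim(mask)
  flat_in <- which(mask)
  colmap <- integer(prod(d))
  colmap[flat_in] <- seq_along(flat_in)
  idx <- arrayInd(flat_in, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbr <- matrix(-1L, length(flat_in), 27L)
  for (k in seq_len(nrow(offs))) {
    p <- sweep(idx, 2, offs[k, ], "+")
    ok <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    res <- rep(-1L, length(flat_in))
    fi <- p[ok, 1] + (p[ok, 2] - 1L) * d[1] + (p[ok, 3] - 1L) * d[1] * d[2]
    vals <- rep(-1L, length(fi))
    inmask <- mask[fi]
    vals[inmask] <- colmap[fi[inmask]] - 1L
    res[ok] <- vals
    nbr[, k] <- res
  }
  nbr
}
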