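# Morphological covariance networks: per-region kernel density estimates of
# gray-matter values compared with a symmetrized Kullback-Leibler
# divergence, mapped to a bounded similarity by exp(-KL_sym).

# Silverman's rule with a degeneracy floor (must mirror the C++ version).
silverman_bw_r <- function(x) {
  n <- length(x)
  spread <- min(sd(x), (quantile(x, 0.75, names = FALSE) -
                          quantile(x, 0.25, names = FALSE)) / 1.34)
  rng <- diff(range(x))
  max(0.9 * spread * n^(-1 / 5), 1e-3 * if (rng > 0) rng else 1)
}

#' Kernel density estimate of a region's voxel values
#'
#' Gaussian KDE with Silverman bandwidth (floored at `1e-3` of the value
#' range, or of 1 for a degenerate region) evaluated on a strictly
#' increasing grid and renormalized so its trapezoidal integral is 1. For
#' divergence computations the two regions under comparison must share a
#' grid; pass one via `grid` (as [morphological_network()] does, using the
#' pooled min/max of both regions padded by 3 bandwidths). Without `grid`,
#' the region's own padded range is used.
#'
#' @param v a [voxel_volume()].
#' @param atlas a [generate_atlas()] result aligned with `v`.
#' @param region region code in `1..R`.
#' @param grid_size number of grid points (default 512).
#' @param grid optional explicit evaluation grid.
#' @return Object of class `region_density`: list `grid`, `pdf`, `region`.
#' @export
region_density <- function(v, atlas, region, grid_size = 512, grid = NULL) {
  vals <- v$data[atlas$labels == region & v$mask]
  if (length(vals) == 0)
    stop("region_density: region ", region, " has no in-mask voxels")
  bw <- silverman_bw_r(vals)
  if (is.null(grid))
    grid <- seq(min(vals) - 3 * bw, max(vals) + 3 * bw,
                length.out = grid_size)
  pdf <- rowMeans(dnorm(outer(grid, vals, "-"), sd = bw))
  pdf <- pdf / trapz_int(grid, pdf)
  structure(list(grid = grid, pdf = pdf, region = region),
            class = "region_density")
}

#' Kullback-Leibler similarity between two region densities
#'
#' `exp(-KL_sym)` with `KL_sym = KL(p||q) + KL(q||p)`, each divergence
#' computed by trapezoidal quadrature after flooring both densities at
#' `1e-12`. Symmetric in its arguments; equal densities give exactly 1.
#'
#' @param p,q [region_density()] objects sharing a grid.
#' @return Scalar similarity in `(0, 1]`.
#' @export
kl_similarity <- function(p, q) {
  if (!isTRUE(all.equal(p$grid, q$grid, tolerance = 0)) &&
      !identical(p$grid, q$grid))
    stop("kl_similarity: densities must share an evaluation grid")
  pp <- pmax(p$pdf, 1e-12)
  qq <- pmax(q$pdf, 1e-12)
  kls <- trapz_int(p$grid, pp * log(pp / qq)) +
    trapz_int(p$grid, qq * log(qq / pp))
  exp(-kls)
}

#' Morphological covariance network of one subject
#'
#' Entry `(i, j)` is the KL similarity between the kernel density estimates
#' of regions `i` and `j` evaluated on their pooled grid (pooled min/max
#' padded by 3 bandwidths, `grid_size` points); the diagonal is 1.
#'
#' @param v a [voxel_volume()] (typically a gray-matter map).
#' @param atlas aligned [generate_atlas()] result.
#' @param grid_size evaluation grid size per pair (default 512).
#' @return A morphological [conn_matrix()].
#' @export
morphological_network <- function(v, atlas, grid_size = 512) {
  stopifnot(inherits(v, "voxel_volume"))
  if (!identical(dim(v$data), dim(atlas$labels)))
    stop("morphological_network: volume and atlas grids differ")
  vals <- lapply(seq_len(atlas$R),
                 function(r) v$data[atlas$labels == r & v$mask])
  empty <- which(vapply(vals, length, 1L) == 0)
  if (length(empty))
    stop("morphological_network: empty region(s): ",
         paste(empty, collapse = ", "))
  S <- cpp_morph_network(vals, as.integer(grid_size))
  diag(S) <- 1
  conn_matrix(S, "morphological", atlas$region_names)
}
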