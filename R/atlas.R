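#' Synthetic parcellation atlas
#'
#' Generates a stand-in for an anatomical parcellation: an ellipsoidal
#' "brain" mask carved into `R` spatially contiguous regions by a seeded
#' Voronoi tessellation (every in-mask voxel takes the label of its nearest
#' region seed; Voronoi cells are convex, hence contiguous on the grid).
#' Labels are the contiguous integers `1..R` with `0` background, and every
#' region is guaranteed at least 8 voxels.
#'
#' @param shape integer length-3 grid dimensions.
#' @param R number of regions (>= 2). The canonical whole-brain analysis
#'   uses 90 regions; small `R` (e.g. 12) keeps test runtimes down.
#' @param seed integer seed; the atlas is deterministic given
#'   `(shape, R, seed)`.
#' @param voxel_size voxel edges in mm.
#' @return An object of class `brain_atlas`: list with `labels` (3D integer
#'   array), `region_names`, `R`, `mask`, `voxel_size`.
#' @examples
#' atl <- generate_atlas(c(12, 12, 12), R = 4, seed = 1)
#' table(atl$labels[atl$labels > 0])
#' @export
generate_atlas <- function(shape, R, seed = 1, voxel_size = c(3, 3, 3)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L))
    stop("generate_atlas: shape must be three dims >= 2")
  if (R < 2) stop("generate_atlas: R must be >= 2")
  ctr <- (shape + 1) / 2
  semi <- shape * 0.42
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  inside <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2 <= 1
  mask <- array(inside, shape)
  nvox <- sum(mask)
  if (nvox < 8 * R)
    stop(sprintf(paste0("generate_atlas: shape %s gives only %d in-mask ",
                        "voxels; cannot host %d regions of >= 8 voxels"),
                 paste(shape, collapse = "x"), nvox, R))
  coords <- as.matrix(g[inside, ])
  labels_flat <- NULL
  with_seed(child_seed(seed, 101L), {
    for (attempt in 1:25) {
      seeds <- coords[sample.int(nvox, R), , drop = FALSE]
      d2 <- matrix(0, nvox, R)
      for (r in seq_len(R))
        d2[, r] <- (coords[, 1] - seeds[r, 1])^2 +
          (coords[, 2] - seeds[r, 2])^2 + (coords[, 3] - seeds[r, 3])^2
      lab <- max.col(-d2, ties.method = "first")
      if (all(tabulate(lab, R) >= 8L)) {
        labels_flat <- lab
        break
      }
    }
  })
  if (is.null(labels_flat))
    stop("generate_atlas: could not place ", R,
         " regions of >= 8 voxels in this grid; use a larger shape")
  labels <- array(0L, shape)
  labels[mask] <- labels_flat
  structure(list(labels = labels,
                 region_names = sprintf("region_%03d", seq_len(R)),
                 R = as.integer(R), mask = mask,
                 voxel_size = as.double(voxel_size)),
            class = "brain_atlas")
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat(sprintf("<brain_atlas> %d regions on %s grid (%d in-mask voxels)\n",
              x$R, paste(dim(x$labels), collapse = "x"), sum(x$mask)))
  invisible(x)
}

# Flat indices (within the full array) of each region's voxels.
region_voxel_index <- function(atlas) {
  lapply(seq_len(atlas$R), function(r) which(atlas$labels == r))
}
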