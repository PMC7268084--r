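#' Functional connectivity matrix
#'
#' Mean time series are extracted per atlas region over the kept frames of
#' a cleaned series, and entry `(i, j)` is their Pearson correlation; the
#' diagonal is exactly 1.
#'
#' @param b a cleaned [bold_series()].
#' @param atlas aligned [generate_atlas()] result; every region needs at
#'   least one in-mask voxel.
#' @return A functional [conn_matrix()].
#' @export
fc_matrix <- function(b, atlas) {
  if (!inherits(b, "bold_series")) stop("fc_matrix: need a bold_series")
  if (!identical(dim(b$mask), dim(atlas$labels)))
    stop("fc_matrix: series and atlas grids differ")
  vox_labels <- as.vector(atlas$labels)[as.vector(b$mask)]
  C <- fc_core(bold_matrix(b), vox_labels, atlas$R)
  conn_matrix(C, "functional", atlas$region_names)
}

fc_core <- function(X, vox_labels, R) {
  M <- vapply(seq_len(R), function(r) {
    cols <- which(vox_labels == r)
    if (length(cols) == 0)
      stop("fc_matrix: region ", r, " has no in-mask voxels")
    rowMeans(X[, cols, drop = FALSE])
  }, numeric(nrow(X)))
  zv <- which(apply(M, 2, var) == 0)
  if (length(zv))
    stop("fc_matrix: zero-variance mean series in region(s): ",
         paste(zv, collapse = ", "))
  C <- cor(M)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C
}
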