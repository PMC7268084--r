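#' 4D BOLD-like time series
#'
#' @param data 4D numeric array `(x, y, z, t)`.
#' @param tr repetition time in seconds.
#' @param mask 3D logical in-brain mask.
#' @param censor logical per-volume keep flag (`TRUE` = keep). Defaults to
#'   all `TRUE`.
#' @return Object of class `bold_series`.
#' @export
bold_series <- function(data, tr, mask = NULL, censor = NULL) {
  if (length(dim(data)) != 4L) stop("bold_series: data must be 4D")
  Tn <- dim(data)[4]
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  if (!identical(dim(mask), dim(data)[1:3]))
    stop("bold_series: mask shape differs from volume shape")
  if (is.null(censor)) censor <- rep(TRUE, Tn)
  if (length(censor) != Tn)
    stop("bold_series: censor length must equal number of volumes")
  if (tr <= 0) stop("bold_series: tr must be positive")
  structure(list(data = data, tr = as.double(tr),
                 mask = array(as.logical(mask), dim(mask)),
                 censor = as.logical(censor)),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %s x %d volumes, TR %.3g s, %d kept\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4],
              x$tr, sum(x$censor)))
  invisible(x)
}

# In-mask voxels as a T x V matrix (column-major voxel order, kept frames).
bold_matrix <- function(b, use_censor = TRUE) {
  d <- dim(b$data)
  m <- matrix(b$data, prod(d[1:3]), d[4])[as.vector(b$mask), , drop = FALSE]
  m <- t(m)
  if (use_censor) m <- m[b$censor, , drop = FALSE]
  m
}
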