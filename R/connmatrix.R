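#' Region-by-region connectivity matrix
#'
#' Shared container for morphological similarity networks (entries in
#' `(0, 1]`, unit diagonal) and functional correlation networks (entries in
#' `[-1, 1]`, unit diagonal). Construction enforces the type invariants.
#'
#' @param values symmetric `R x R` numeric matrix.
#' @param kind `"morphological"` or `"functional"`.
#' @param region_names character length `R`.
#' @return Object of class `conn_matrix`.
#' @export
conn_matrix <- function(values, kind = c("morphological", "functional"),
                        region_names = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  R <- nrow(values)
  if (ncol(values) != R) stop("conn_matrix: values must be square")
  if (max(abs(values - t(values))) > 1e-12)
    stop("conn_matrix: values not symmetric to 1e-12")
  values <- (values + t(values)) / 2
  if (max(abs(diag(values) - 1)) > 0)
    stop("conn_matrix: diagonal must be exactly 1")
  if (kind == "morphological" && (any(values <= 0) || any(values > 1)))
    stop("conn_matrix: morphological entries must lie in (0, 1]")
  if (kind == "functional" && any(abs(values) > 1))
    stop("conn_matrix: functional entries must lie in [-1, 1]")
  if (is.null(region_names)) region_names <- sprintf("region_%03d",
                                                     seq_len(R))
  dimnames(values) <- list(region_names, region_names)
  structure(list(values = values, kind = kind,
                 region_names = region_names),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %s, %d x %d\n", x$kind,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Vectorize a connectivity matrix for classification
#'
#' Returns the strict upper triangle in fixed row-major order:
#' `(1,2), (1,3), ..., (1,R), (2,3), ...` - `R(R-1)/2` features, so the
#' duplicated lower triangle and the constant diagonal never enter a model.
#'
#' @param cm a [conn_matrix()].
#' @return Named numeric vector of length `R(R-1)/2`.
#' @export
conn_vector <- function(cm) {
  m <- cm$values
  idx <- which(upper.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- m[idx]
  names(out) <- paste(cm$region_names[idx[, 1]], cm$region_names[idx[, 2]],
                      sep = "--")
  out
}

# Rebuild a symmetric R x R matrix (zero diagonal) from a row-major
# upper-triangle vector, as emitted by conn_vector().
unvectorize_conn <- function(v, R) {
  if (length(v) != R * (R - 1) / 2)
    stop("unvectorize_conn: length ", length(v), " != R(R-1)/2 for R = ", R)
  m <- matrix(0, R, R)
  k <- 1L
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    m[i, j] <- v[k]
    m[j, i] <- v[k]
    k <- k + 1L
  }
  m
}
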