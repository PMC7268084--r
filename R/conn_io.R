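#' Read and write connectivity matrices as TSV
#'
#' Plain-text serialization with region names as header row and first
#' column, suitable for versioning and external tools.
#'
#' @param cm a [conn_matrix()].
#' @param path output/input file path.
#' @param kind matrix kind to assume when reading.
#' @return `write_conn_tsv` returns `path` invisibly; `read_conn_tsv`
#'   returns a [conn_matrix()].
#' @export
write_conn_tsv <- function(cm, path) {
  if (!inherits(cm, "conn_matrix")) stop("write_conn_tsv: need conn_matrix")
  df <- data.frame(region = cm$region_names, cm$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conn_tsv
#' @export
read_conn_tsv <- function(path, kind = c("morphological", "functional")) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- NULL; colnames(m) <- NULL
  conn_matrix(m, match.arg(kind), region_names = df[[1]])
}
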