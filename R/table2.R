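#' Published per-dataset classification metrics
#'
#' Loads the shipped table of per-dataset balanced accuracy, sensitivity
#' and specificity for the six measures and their combinations across the
#' five multi-site schizophrenia datasets (the published reference results
#' this package's aggregation reproduces).
#' These values serve as inputs to [aggregate_summary()] when reproducing
#' the published aggregation arithmetic.
#'
#' @return data.frame: `measure`, `dataset`, `bac`, `sen`, `spec`.
#' @export
published_metrics <- function() {
  read.delim(system.file("extdata", "table2_metrics.tsv",
                         package = "neurofuse"),
             stringsAsFactors = FALSE, check.names = FALSE)
}
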