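#' Region attribution for a connectome-based measure
#'
#' Reconstructs the symmetric matrix of absolute weights from an
#' upper-triangle weight vector (as trained on [conn_vector()] features)
#' and assigns each region the mean of its `R - 1` off-diagonal absolute
#' weights - the average strength with which the region's connections
#' enter the decision function.
#'
#' @param weight_vector numeric, length `R(R-1)/2`, row-major upper
#'   triangle.
#' @param R region count.
#' @return Numeric length-`R` vector of non-negative region values.
#' @export
region_weights_matrix_measure <- function(weight_vector, R) {
  W <- abs(unvectorize_conn(weight_vector, R))
  rowSums(W) / (R - 1)
}

#' Region attribution for a voxel-wise measure
#'
#' Mean absolute weight over each atlas region's in-mask voxels. The
#' weight map may be given as a [voxel_volume()] or as the flat in-mask
#' weight vector in [voxel_features()] order.
#'
#' @param weight_map `voxel_volume` of weights, or numeric vector of
#'   length `sum(atlas$mask)`.
#' @param atlas a [generate_atlas()] result.
#' @return Numeric length-`R`; a region with no in-mask voxels gets `NA`
#'   (flagged missing, not zero).
#' @export
region_weights_voxel_measure <- function(weight_map, atlas) {
  w <- if (inherits(weight_map, "voxel_volume"))
    weight_map$data[weight_map$mask] else as.numeric(weight_map)
  vox_lab <- as.vector(atlas$labels)[as.vector(atlas$mask)]
  if (length(w) != length(vox_lab))
    stop("region_weights_voxel_measure: weight vector length ", length(w),
         " does not match the atlas mask (", length(vox_lab), ")")
  vapply(seq_len(atlas$R), function(r) {
    v <- abs(w[vox_lab == r])
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
}

#' Rank regions by mean attributed weight across datasets
#'
#' Region values are averaged over folds within each dataset (the caller
#' usually did this already), then across datasets; the `k` regions with
#' the highest mean are reported with their per-dataset values, ties
#' broken by region index.
#'
#' @param tables regions x datasets numeric matrix (or a list of
#'   per-dataset region vectors).
#' @param k rows to report (default 10; truncated to `R` with a warning).
#' @param region_names optional region names.
#' @return data.frame: region, one column per dataset, `mean`, sorted
#'   descending.
#' @export
top_regions <- function(tables, k = 10, region_names = NULL) {
  if (is.list(tables) && !is.data.frame(tables))
    tables <- do.call(cbind, tables)
  tables <- as.matrix(tables)
  R <- nrow(tables)
  if (k > R) {
    warning("top_regions: k = ", k, " > ", R, " regions; truncating")
    k <- R
  }
  if (is.null(colnames(tables)))
    colnames(tables) <- sprintf("dataset_%d", seq_len(ncol(tables)))
  if (is.null(region_names)) region_names <- rownames(tables) %||%
      sprintf("region_%03d", seq_len(R))
  mu <- rowMeans(tables)
  ord <- order(-mu, seq_len(R))[seq_len(k)]
  out <- data.frame(region = region_names[ord], tables[ord, , drop = FALSE],
                    mean = mu[ord], row.names = NULL,
                    check.names = FALSE)
  out
}

#' Aggregate per-dataset classification results
#'
#' Reproduces the summary arithmetic of a multi-dataset report: for each
#' measure (or measure combination) the `"Average"` row is the unweighted
#' arithmetic mean of the per-dataset values, and modality-level means are
#' the unweighted mean of the three single-measure averages within the
#' modality (structural: StructM, GM, WM; functional: FuncM, ReHo, ALFF).
#' All reported values are rounded half away from zero to 2 decimals.
#'
#' @param results data.frame with columns `measure`, `dataset`, `bac`,
#'   `sen`, `spec` (percent).
#' @return List: `summary` (the input rows plus an `Average` row per
#'   measure), `modality_means` (named numeric: `structural`,
#'   `functional`, when the constituent measures are present). Missing
#'   dataset cells average over the available ones and are flagged in the
#'   `note` attribute.
#' @export
aggregate_summary <- function(results) {
  need <- c("measure", "dataset", "bac")
  if (!all(need %in% names(results)))
    stop("aggregate_summary: results needs columns measure/dataset/bac")
  if (!"sen" %in% names(results)) results$sen <- NA_real_
  if (!"spec" %in% names(results)) results$spec <- NA_real_
  datasets <- unique(results$dataset)
  note <- character(0)
  rows <- list()
  for (m in unique(results$measure)) {
    sub <- results[results$measure == m, , drop = FALSE]
    if (length(setdiff(datasets, sub$dataset)))
      note <- c(note, paste0(m, ": Average over ", nrow(sub), " of ",
                             length(datasets), " datasets"))
    rows[[m]] <- data.frame(
      measure = m, dataset = "Average",
      bac = round_half_up(mean(sub$bac)),
      sen = round_half_up(mean(sub$sen)),
      spec = round_half_up(mean(sub$spec)))
  }
  avg <- do.call(rbind, rows)
  summary <- rbind(results[, c("measure", "dataset", "bac", "sen", "spec")],
                   avg)
  rownames(summary) <- NULL
  get_avg <- function(m) avg$bac[avg$measure == m]
  modality <- c(structural = NA_real_, functional = NA_real_)
  if (all(c("StructM", "GM", "WM") %in% avg$measure))
    modality["structural"] <- round_half_up(
      mean(c(get_avg("StructM"), get_avg("GM"), get_avg("WM"))))
  if (all(c("FuncM", "ReHo", "ALFF") %in% avg$measure))
    modality["functional"] <- round_half_up(
      mean(c(get_avg("FuncM"), get_avg("ReHo"), get_avg("ALFF"))))
  out <- list(summary = summary, modality_means = modality)
  if (length(note)) attr(out, "note") <- note
  out
}
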