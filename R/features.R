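#' Per-measure feature table
#'
#' A subjects-by-features matrix for one measure, row-aligned with the
#' cohort's metadata.
#'
#' @param matrix numeric subjects x features matrix (finite).
#' @param measure one of `"GM"`, `"WM"`, `"StructM"`, `"ReHo"`, `"ALFF"`,
#'   `"FuncM"` (free-form labels are tolerated).
#' @param subject_ids character row identifiers.
#' @param feature_labels optional character column labels.
#' @return Object of class `measure_features`.
#' @export
measure_features <- function(matrix, measure, subject_ids,
                             feature_labels = NULL) {
  matrix <- as.matrix(matrix)
  if (any(!is.finite(matrix)))
    stop("measure_features: non-finite entries in measure ", measure)
  if (length(subject_ids) != nrow(matrix))
    stop("measure_features: subject_ids do not match rows")
  if (is.null(feature_labels))
    feature_labels <- colnames(matrix) %||%
      sprintf("f%05d", seq_len(ncol(matrix)))
  dimnames(matrix) <- NULL
  structure(list(matrix = matrix, measure = measure,
                 subject_ids = as.character(subject_ids),
                 feature_labels = as.character(feature_labels)),
            class = "measure_features")
}

#' @export
print.measure_features <- function(x, ...) {
  cat(sprintf("<measure_features> %s: %d subjects x %d features\n",
              x$measure, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

subset_measure <- function(X, rows) {
  measure_features(X$matrix[rows, , drop = FALSE], X$measure,
                   X$subject_ids[rows], X$feature_labels)
}

#' Extract all six measures from a cohort
#'
#' Runs the full feature pathway on every subject: 6 mm FWHM smoothing and
#' voxel-wise vectorization of gray and white matter, the KL-similarity
#' morphological network of the smoothed gray-matter map, BOLD cleaning
#' (discard, scrub, detrend, bandpass, nuisance regression), ReHo, ALFF and
#' the regional Pearson connectome. Subjects whose motion exceeds the
#' exclusion limits are dropped (with a message).
#'
#' @param cohort a [generate_cohort()] (or [read_cohort()]) result.
#' @param cfg a [cleaning_config()].
#' @param fwhm_mm structural smoothing kernel (default 6 mm).
#' @param kde_grid KDE grid size for the morphological network.
#' @return List: `measures` (named list of [measure_features()]: GM, WM,
#'   StructM, ReHo, ALFF, FuncM), `meta` (metadata of retained subjects),
#'   `excluded` (ids of motion-excluded subjects).
#' @export
compute_measures <- function(cohort, cfg = cleaning_config(), fwhm_mm = 6,
                             kde_grid = 512) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n <- nrow(cohort$meta)
  atlas <- cohort$atlas
  do_struct <- !is.null(cohort$gm[[1]])
  do_bold <- !is.null(cohort$bold[[1]])
  rows <- list(GM = list(), WM = list(), StructM = list(), ReHo = list(),
               ALFF = list(), FuncM = list())
  excluded <- character(0)
  keep <- logical(n)
  nbr <- if (do_bold) neighbor_index(atlas$mask)
  vox_lab <- as.vector(atlas$labels)[as.vector(atlas$mask)]
  edge_names <- if (atlas$R >= 2) {
    cm0 <- conn_matrix(diag(atlas$R) * 0 + diag(atlas$R), "functional",
                       atlas$region_names)
    names(conn_vector(cm0))
  }
  for (s in seq_len(n)) {
    if (do_bold) {
      cl <- clean_bold(cohort$bold[[s]], cohort$motion[[s]], cfg, atlas)
      if (cl$excluded) {
        excluded <- c(excluded, cohort$meta$participant_id[s])
        next
      }
      X <- bold_matrix(cl$bold)
      rows$ReHo[[s]] <- reho_core(X, nbr)
      rows$ALFF[[s]] <- alff_core(X, cl$bold$tr, cfg$band)
      fcv <- fc_core(X, vox_lab, atlas$R)
      v <- t(fcv)[lower.tri(fcv)] # row-major upper triangle
      names(v) <- edge_names
      rows$FuncM[[s]] <- v
    }
    if (do_struct) {
      gsm <- smooth_volume(cohort$gm[[s]], fwhm_mm)
      wsm <- smooth_volume(cohort$wm[[s]], fwhm_mm)
      rows$GM[[s]] <- voxel_features(gsm)
      rows$WM[[s]] <- voxel_features(wsm)
      rows$StructM[[s]] <- conn_vector(morphological_network(gsm, atlas,
                                                             kde_grid))
    }
    keep[s] <- TRUE
  }
  if (length(excluded))
    message("compute_measures: excluded for motion: ",
            paste(excluded, collapse = ", "))
  meta <- cohort$meta[keep, , drop = FALSE]
  ids <- meta$participant_id
  out <- list()
  sets <- c(if (do_struct) c("GM", "WM", "StructM"),
            if (do_bold) c("ReHo", "ALFF", "FuncM"))
  for (m in sets)
    out[[m]] <- measure_features(do.call(rbind, rows[[m]][keep]), m, ids)
  list(measures = out, meta = meta, excluded = excluded)
}
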