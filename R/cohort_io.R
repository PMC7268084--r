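#' Write a cohort to a BIDS-flavoured file tree
#'
#' Writes `participants.tsv` (participant_id, group, age, sex, site),
#' `atlas.nii` (int32 labels), per-subject `*_gm.nii` / `*_wm.nii` /
#' `*_bold.nii` (float64, so round trips are bit-exact), per-subject motion
#' tables (`*_motion.tsv`: trans_x/y/z mm, rot_x/y/z rad), and the
#' generator truth as a plain-text `truth.dput`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param directory target directory.
#' @param overwrite refuse to write into an existing non-empty directory
#'   unless `TRUE`.
#' @return `directory`, invisibly; writes are logged via `message()`.
#' @export
write_cohort <- function(cohort, directory, overwrite = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (dir.exists(directory) && length(list.files(directory)) > 0 &&
      !overwrite)
    stop("write_cohort: directory ", directory,
         " exists and is non-empty; pass overwrite = TRUE")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  vs <- cohort$atlas$voxel_size
  write.table(cohort$meta, file.path(directory, "participants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_nifti(cohort$atlas$labels, file.path(directory, "atlas.nii"),
              voxel_size = vs, datatype = "int32")
  for (s in seq_len(nrow(cohort$meta))) {
    id <- cohort$meta$participant_id[s]
    if (!is.null(cohort$gm[[s]])) {
      write_nifti(cohort$gm[[s]]$data,
                  file.path(directory, paste0(id, "_gm.nii")),
                  voxel_size = vs)
      write_nifti(cohort$wm[[s]]$data,
                  file.path(directory, paste0(id, "_wm.nii")),
                  voxel_size = vs)
    }
    if (!is.null(cohort$bold[[s]])) {
      write_nifti(cohort$bold[[s]]$data,
                  file.path(directory, paste0(id, "_bold.nii")),
                  voxel_size = vs, tr = cohort$bold[[s]]$tr)
      write.table(as.data.frame(cohort$motion[[s]]),
                  file.path(directory, paste0(id, "_motion.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  dput(cohort$truth, file.path(directory, "truth.dput"))
  message("write_cohort: wrote ", nrow(cohort$meta), " subjects to ",
          directory)
  invisible(directory)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory cohort directory.
#' @return A `synthetic_cohort` (with `truth` when present).
#' @export
read_cohort <- function(directory) {
  meta <- read.delim(file.path(directory, "participants.tsv"),
                     stringsAsFactors = FALSE)
  atl_nii <- read_nifti(file.path(directory, "atlas.nii"))
  labels <- atl_nii$data
  R <- max(labels)
  atlas <- structure(list(labels = labels,
                          region_names = sprintf("region_%03d", seq_len(R)),
                          R = as.integer(R), mask = labels > 0,
                          voxel_size = atl_nii$voxel_size),
                     class = "brain_atlas")
  n <- nrow(meta)
  gm <- wm <- bold <- motion <- vector("list", n)
  for (s in seq_len(n)) {
    id <- meta$participant_id[s]
    fg <- file.path(directory, paste0(id, "_gm.nii"))
    if (file.exists(fg)) {
      gm[[s]] <- voxel_volume(read_nifti(fg)$data, atlas$mask,
                              atlas$voxel_size)
      wm[[s]] <- voxel_volume(
        read_nifti(file.path(directory, paste0(id, "_wm.nii")))$data,
        atlas$mask, atlas$voxel_size)
    }
    fb <- file.path(directory, paste0(id, "_bold.nii"))
    if (file.exists(fb)) {
      nii <- read_nifti(fb)
      bold[[s]] <- bold_series(nii$data, nii$tr, atlas$mask)
      motion[[s]] <- as.matrix(read.delim(
        file.path(directory, paste0(id, "_motion.tsv"))))
    }
  }
  truth <- NULL
  ft <- file.path(directory, "truth.dput")
  if (file.exists(ft)) truth <- dget(ft)
  structure(list(meta = meta, gm = gm, wm = wm, bold = bold,
                 motion = motion, atlas = atlas, truth = truth),
            class = "synthetic_cohort")
}
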