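#' Cleaning configuration for resting-state series
#'
#' Bundles the denoising contract: initial volume discard, scrubbing
#' threshold, bandpass edges, gross-motion exclusion limits, the nuisance
#' set, and the FD head radius.
#'
#' @param n_discard initial volumes dropped (default 10).
#' @param band bandpass edges in Hz (default `c(0.01, 0.08)`).
#' @param fd_thresh scrubbing threshold in mm (default 0.5).
#' @param max_translation,max_rotation_deg subject exclusion limits:
#'   any absolute translation > 1.5 mm or rotation > 1.5 degrees.
#' @param nuisance subset of `c("global", "wm", "csf", "friston24")`.
#' @param head_radius_mm FD rotational radius (default 50).
#' @param filter_order Butterworth prototype order (default 4).
#' @param wm_region,csf_region atlas label codes used as white-matter and
#'   CSF proxy masks on synthetic data; default to the last and second-last
#'   region codes.
#' @param alff_on_unfiltered if `TRUE`, ALFF is computed on the detrended
#'   but unfiltered series (the common alternative convention); default
#'   `FALSE` computes it on the fully cleaned series.
#' @return Object of class `cleaning_config`.
#' @export
cleaning_config <- function(n_discard = 10, band = c(0.01, 0.08),
                            fd_thresh = 0.5, max_translation = 1.5,
                            max_rotation_deg = 1.5,
                            nuisance = c("global", "wm", "csf", "friston24"),
                            head_radius_mm = 50, filter_order = 4,
                            wm_region = NULL, csf_region = NULL,
                            alff_on_unfiltered = FALSE) {
  if (!(band[1] > 0 && band[1] < band[2]))
    stop("cleaning_config: need 0 < band[1] < band[2]")
  structure(list(n_discard = n_discard, band = band, fd_thresh = fd_thresh,
                 max_translation = max_translation,
                 max_rotation_deg = max_rotation_deg, nuisance = nuisance,
                 head_radius_mm = head_radius_mm,
                 filter_order = filter_order, wm_region = wm_region,
                 csf_region = csf_region,
                 alff_on_unfiltered = alff_on_unfiltered),
            class = "cleaning_config")
}

#' Clean a BOLD series
#'
#' Applies the denoising pipeline in a fixed order: (1) discard the first
#' `n_discard` volumes; (2) censor volumes with framewise displacement above
#' `fd_thresh`; (3) linear detrend; (4) zero-phase Butterworth bandpass;
#' (5) regress out the nuisance set (global / white-matter-proxy /
#' CSF-proxy mean series plus the Friston-24 motion expansion), each
#' regressor detrended and filtered identically to the data. The subject
#' exclusion flag is raised when any post-discard absolute translation
#' exceeds `max_translation` mm or any rotation exceeds `max_rotation_deg`
#' degrees; the flagged subject is still cleaned so callers decide.
#'
#' @param b a [bold_series()].
#' @param m `T x 6` motion table aligned with the pre-discard series
#'   (translations mm, rotations radians).
#' @param cfg a [cleaning_config()].
#' @param atlas optional [generate_atlas()] result supplying the
#'   white-matter/CSF proxy label regions; without it only the global mean
#'   (plus motion) is regressed.
#' @return List: `bold` (cleaned `bold_series` holding the surviving
#'   frames), `excluded` (logical), `fd` (post-discard FD series),
#'   `n_censored`.
#' @export
clean_bold <- function(b, m, cfg = cleaning_config(), atlas = NULL) {
  stopifnot(inherits(b, "bold_series"))
  m <- as.matrix(m)
  Tn <- dim(b$data)[4]
  if (nrow(m) != Tn)
    stop("clean_bold: motion rows (", nrow(m), ") != volumes (", Tn, ")")
  nyq <- 1 / (2 * b$tr)
  if (cfg$band[2] >= nyq)
    stop("clean_bold: band upper edge must be below Nyquist (", nyq, " Hz)")
  keep0 <- seq_len(Tn) > cfg$n_discard
  m_post <- m[keep0, , drop = FALSE]
  excluded <- any(abs(m_post[, 1:3]) > cfg$max_translation) ||
    any(abs(m_post[, 4:6]) > cfg$max_rotation_deg * pi / 180)
  fd <- framewise_displacement(m_post, cfg$head_radius_mm)
  keep_fd <- fd <= cfg$fd_thresh
  n_surv <- sum(keep_fd)
  if (n_surv < 40)
    stop("clean_bold: insufficient volumes (", n_surv,
         " survive discard+scrubbing; need >= 40)")

  X <- bold_matrix(bold_series(b$data[, , , keep0, drop = FALSE], b$tr,
                               b$mask))[keep_fd, , drop = FALSE]
  flt <- butter_bandpass(cfg$band[1], cfg$band[2], 1 / b$tr,
                         cfg$filter_order)
  Xc <- filtfilt(flt$b, flt$a, detrend_linear(X))

  regs <- NULL
  if (!is.null(atlas))
    vox_labels <- as.vector(atlas$labels)[as.vector(b$mask)]
  if ("global" %in% cfg$nuisance)
    regs <- cbind(regs, global = rowMeans(X))
  if (!is.null(atlas)) {
    wm_r <- cfg$wm_region %||% atlas$R
    csf_r <- cfg$csf_region %||% (atlas$R - 1L)
    if ("wm" %in% cfg$nuisance && any(vox_labels == wm_r))
      regs <- cbind(regs, wm = rowMeans(X[, vox_labels == wm_r,
                                          drop = FALSE]))
    if ("csf" %in% cfg$nuisance && any(vox_labels == csf_r))
      regs <- cbind(regs, csf = rowMeans(X[, vox_labels == csf_r,
                                           drop = FALSE]))
  }
  if ("friston24" %in% cfg$nuisance) {
    f24 <- friston24(m_post)[keep_fd, , drop = FALSE]
    regs <- cbind(regs, f24)
  }
  if (!is.null(regs)) {
    regs <- filtfilt(flt$b, flt$a, detrend_linear(regs))
    # lm.fit tolerates the rank deficiency a detrended/filtered Friston-24
    # block routinely has
    Xc <- lm.fit(cbind(1, regs), Xc)$residuals
  }

  out <- array(0, c(dim(b$data)[1:3], n_surv))
  flat <- matrix(out, ncol = n_surv)
  flat[as.vector(b$mask), ] <- t(Xc)
  out <- array(flat, c(dim(b$data)[1:3], n_surv))
  list(bold = bold_series(out, b$tr, b$mask), excluded = excluded,
       fd = fd, n_censored = sum(!keep_fd))
}
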