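#' Ground-truth effect specification for synthetic cohorts
#'
#' Declares the group differences, confound slopes and site nuisances a
#' synthetic cohort carries, so recovery can be tested against a known
#' truth.
#'
#' * `struct_effect_d`: standardized (Cohen's d on the across-subject
#'   distribution of region-mean values) additive shift applied to patients'
#'   gray matter in the affected regions; white matter receives 0.7 of it.
#' * `coherence_shift`: additive change, for patients, of the shared-signal
#'   fraction of voxels in affected regions (drives ReHo).
#' * `amplitude_shift`: multiplicative gain (> 0) on patients' BOLD series
#'   in affected regions (drives ALFF; rank- and correlation-invariant, so
#'   ReHo and connectivity are untouched by construction).
#' * `fc_shift`: additive change of the latent inter-regional correlation on
#'   affected edges for patients; all implied correlations must stay inside
#'   (-1, 1) and the implied matrix positive definite.
#' * `confound_slopes`: age/sex effects: `gm_age`, `gm_sex`, `wm_age`,
#'   `wm_sex` (additive per year / for males, in map units) and `bold_age`,
#'   `bold_sex` (log-gain applied to even-numbered regions, so normalized
#'   functional maps retain a confound pattern).
#' * `site_offsets`: named per-site list of nuisances, each regionally
#'   patterned the way scanner effects are in practice (spatially uniform
#'   offsets are invisible to linear contrasts): `struct_add` (additive on
#'   odd regions), `struct_gain` (global gain), `coherence_add` (added
#'   shared-signal fraction, odd regions), `amp_gain_odd` (amplitude gain
#'   on odd regions), `fc_add` (checkerboard-signed addition to the latent
#'   correlations).
#'
#' @param struct_effect_d,coherence_shift,amplitude_shift,fc_shift scalars
#'   as described above.
#' @param affected_regions integer region codes carrying group effects
#'   (default `1:4`).
#' @param affected_edges 2-column matrix of region pairs carrying `fc_shift`
#'   (default: all pairs within `affected_regions`).
#' @param confound_slopes named list, see above.
#' @param site_offsets named list of per-site lists, see above.
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(struct_effect_d = 0, coherence_shift = 0,
                        amplitude_shift = 1, fc_shift = 0,
                        affected_regions = 1:4, affected_edges = NULL,
                        confound_slopes = list(), site_offsets = list()) {
  if (amplitude_shift <= 0) stop("effect_spec: amplitude_shift must be > 0")
  if (is.null(affected_edges) && length(affected_regions) >= 2)
    affected_edges <- t(utils::combn(affected_regions, 2))
  slopes <- utils::modifyList(
    list(gm_age = 0, gm_sex = 0, wm_age = 0, wm_sex = 0,
         bold_age = 0, bold_sex = 0), confound_slopes)
  structure(list(struct_effect_d = struct_effect_d,
                 coherence_shift = coherence_shift,
                 amplitude_shift = amplitude_shift, fc_shift = fc_shift,
                 affected_regions = as.integer(affected_regions),
                 affected_edges = affected_edges,
                 confound_slopes = slopes, site_offsets = site_offsets),
            class = "effect_spec")
}

#' Canonical disease-effect specification
#'
#' The package's documented default group-effect magnitudes for synthetic
#' patients: structural shift `struct_effect_d` (default 1.5 standardized
#' units on region means), within-region coherence raised by 0.3 (0.45 to
#' 0.75 shared-signal fraction), in-band amplitude gain 1.5, and latent
#' connectivity raised by 0.45 (0.2 to 0.65) on edges among the affected
#' regions. The functional magnitudes are chosen so each handle remains
#' clearly detectable after the cleaning contract - global-signal
#' regression in particular attenuates injected connectivity differences,
#' a well-known property of that step.
#'
#' @param struct_effect_d structural effect size (default 1.5).
#' @param ... passed on to [effect_spec()].
#' @return An [effect_spec()].
#' @export
disease_effects <- function(struct_effect_d = 1.5, ...) {
  effect_spec(struct_effect_d = struct_effect_d, coherence_shift = 0.3,
              amplitude_shift = 1.5, fc_shift = 0.45, ...)
}

#' Default generator noise scales
#'
#' @param struct_subject_sd across-subject SD of the structural baseline.
#' @param struct_voxel_sd voxel-level structural noise SD.
#' @param base_coherence control-group shared-signal fraction of a voxel's
#'   variance within its region.
#' @param base_fc control-group latent correlation between any two regions.
#' @param broadband_frac fraction of latent variance given to the AR(1)
#'   broadband component (the rest is 0.01-0.08 Hz band-limited).
#' @param motion_walk_trans,motion_walk_rot per-frame random-walk SDs
#'   (mm / radians).
#' @param motion_spike_prob,motion_spike_mm frame-wise probability and size
#'   of injected translation spikes.
#' @return Object of class `noise_scales` (a named list).
#' @export
noise_scales <- function(struct_subject_sd = 0.05, struct_voxel_sd = 0.08,
                         base_coherence = 0.45, base_fc = 0.2,
                         broadband_frac = 0.1,
                         motion_walk_trans = 0.01, motion_walk_rot = 2e-4,
                         motion_spike_prob = 0.01, motion_spike_mm = 0.8) {
  structure(as.list(environment()), class = "noise_scales")
}

# Per-site nuisance builder used by the site-transfer experiments.
#' Per-site nuisance offsets
#'
#' Convenience builder for [effect_spec()]'s `site_offsets`. `strength
#' = "none"` gives identical sites; `"large"` gives offsets big enough to
#' dominate group effects (the regime in which cross-site transfer
#' collapses).
#'
#' @param sites character site names.
#' @param strength `"none"` or `"large"`.
#' @return Named list of per-site offset lists.
#' @export
make_site_offsets <- function(sites, strength = c("none", "large")) {
  strength <- match.arg(strength)
  out <- list()
  for (i in seq_along(sites)) {
    if (strength == "none" || i == 1) {
      out[[sites[i]]] <- list(struct_add = 0, struct_gain = 1,
                              coherence_add = 0, amp_gain_odd = 1,
                              fc_add = 0)
    } else {
      sgn <- if (i %% 2 == 0) 1 else -1
      out[[sites[i]]] <- list(struct_add = 0.2 * sgn, struct_gain = 1.2,
                              coherence_add = 0.25 * sgn,
                              amp_gain_odd = 2, fc_add = 0.25 * sgn)
    }
  }
  out
}

site_of <- function(effects, site) {
  off <- effects$site_offsets[[site]]
  utils::modifyList(list(struct_add = 0, struct_gain = 1, coherence_add = 0,
                         amp_gain_odd = 1, fc_add = 0), off %||% list())
}

# Latent correlation matrix for one group at one site. Both the site
# nuisance (checkerboard over region parity) and the group edge shifts
# (alternating over edges) change sign across entries, so neither is a
# pure common mode that global-signal regression would simply remove.
latent_sigma <- function(Rn, base_fc, fc_add, edges, fc_shift) {
  alt <- outer(seq_len(Rn), seq_len(Rn), function(i, j) (-1)^(i + j))
  S <- base_fc + fc_add * alt
  diag(S) <- 1
  if (!is.null(edges) && fc_shift != 0) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      S[i, j] <- S[i, j] + fc_shift * (if (k %% 2 == 0) -1 else 1)
      S[j, i] <- S[i, j]
    }
  }
  if (any(abs(S[upper.tri(S)]) >= 1))
    stop("generate_cohort: implied latent correlations leave (-1, 1)")
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-8)
    stop("generate_cohort: implied latent correlation matrix not positive ",
         "definite")
  S
}

#' Generate a multimodal synthetic cohort
#'
#' Draws a two-group (patients/controls), optionally multi-site cohort on a
#' shared atlas grid. Structural maps are subject baseline + regional group
#' shifts + age/sex/site terms + voxel noise; BOLD series follow a
#' latent-signal model (per-region band-limited 0.01-0.08 Hz signal plus a
#' small AR(1) broadband part, mixed into member voxels, with the
#' shared-signal fraction controlling within-region coherence and a latent
#' correlation matrix controlling region-to-region connectivity); motion
#' traces are small random walks with optional spikes. Deterministic given
#' the seed.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param atlas a [generate_atlas()] result.
#' @param effects an [effect_spec()].
#' @param noise a [noise_scales()].
#' @param T timepoints (>= 40 + the standard 10-volume discard).
#' @param tr repetition time, seconds.
#' @param sites character vector of site names; subjects are dealt to sites
#'   round-robin within group.
#' @param age_group_shift years added to patients' mean age (induces an
#'   age-group confound when nonzero).
#' @param modalities any of `"struct"`, `"bold"`; dropping `"bold"` makes
#'   structural-only cohorts cheap to replicate.
#' @param seed integer seed.
#' @return Object of class `synthetic_cohort`: list with `meta`
#'   (data.frame: participant_id, group, age, sex, site), `gm`, `wm`
#'   (lists of [voxel_volume()]), `bold` (list of [bold_series()]),
#'   `motion` (list of `T x 6` matrices), `atlas`, and `truth`.
#' @export
generate_cohort <- function(n_per_group, atlas, effects = effect_spec(),
                            noise = noise_scales(), T = 120, tr = 2,
                            sites = "site1", age_group_shift = 0,
                            modalities = c("struct", "bold"), seed = 1) {
  stopifnot(inherits(atlas, "brain_atlas"))
  if (n_per_group < 2) stop("generate_cohort: n_per_group must be >= 2")
  if (T < 40) stop("generate_cohort: T must be >= 40")
  n <- 2L * n_per_group
  group <- rep(c("patient", "control"), each = n_per_group)
  site <- rep_len(rep(sites, length.out = n_per_group), n)
  meta <- with_seed(child_seed(seed, 1L), data.frame(
    participant_id = sprintf("sub-%03d", seq_len(n)),
    group = group,
    age = round(pmin(pmax(rnorm(n, 32 + ifelse(group == "patient",
                                               age_group_shift, 0), 9),
                          18), 65), 1),
    sex = ifelse(runif(n) < 0.55, "M", "F"),
    site = site, stringsAsFactors = FALSE))

  d <- dim(atlas$labels)
  mask <- atlas$mask
  vox_lab <- as.vector(atlas$labels)[as.vector(mask)]
  nvox <- length(vox_lab)
  n_r <- tabulate(vox_lab, atlas$R)
  # deterministic smooth spatial profile shared by all subjects
  idx <- arrayInd(which(mask), d)
  profile <- 0.05 * sin(2 * pi * idx[, 1] / d[1]) *
    cos(2 * pi * idx[, 2] / d[2]) + 0.03 * idx[, 3] / d[3]
  sig_mean <- sqrt(noise$struct_subject_sd^2 +
                     noise$struct_voxel_sd^2 / n_r)
  sl <- effects$confound_slopes
  aff <- effects$affected_regions
  gm <- wm <- bold <- motion <- vector("list", n)

  if ("bold" %in% modalities) {
    Sig <- list(
      control = lapply(stats::setNames(sites, sites), function(s)
        chol(latent_sigma(atlas$R, noise$base_fc, site_of(effects, s)$fc_add,
                          NULL, 0))),
      patient = lapply(stats::setNames(sites, sites), function(s)
        chol(latent_sigma(atlas$R, noise$base_fc, site_of(effects, s)$fc_add,
                          effects$affected_edges, effects$fc_shift))))
    flt <- butter_bandpass(0.01, 0.08, 1 / tr, 4)
  }

  for (s in seq_len(n)) {
    so <- site_of(effects, meta$site[s])
    is_pat <- meta$group[s] == "patient"
    age_c <- meta$age[s] - 32
    male <- as.numeric(meta$sex[s] == "M")

    if ("struct" %in% modalities) {
      reg_shift_gm <- reg_shift_wm <- rep(0, atlas$R)
      if (is_pat && effects$struct_effect_d != 0) {
        reg_shift_gm[aff] <- effects$struct_effect_d * sig_mean[aff]
        reg_shift_wm[aff] <- 0.7 * effects$struct_effect_d * sig_mean[aff]
      }
      # the site offset is regionally patterned (odd regions), as scanner
      # effects are in practice; a spatially uniform offset is invisible
      # to a linear contrast and would not perturb transfer
      site_term <- so$struct_add * (vox_lab %% 2 == 1)
      vals <- with_seed(child_seed(seed, 2L, s), {
        base_g <- 0.6 + rnorm(1, 0, noise$struct_subject_sd)
        base_w <- 0.4 + rnorm(1, 0, noise$struct_subject_sd)
        g <- base_g + profile + reg_shift_gm[vox_lab] +
          sl$gm_age * age_c + sl$gm_sex * male + site_term +
          rnorm(nvox, 0, noise$struct_voxel_sd)
        w <- base_w + 0.5 * profile + reg_shift_wm[vox_lab] +
          sl$wm_age * age_c + sl$wm_sex * male + site_term +
          rnorm(nvox, 0, noise$struct_voxel_sd)
        list(g = so$struct_gain * g, w = so$struct_gain * w)
      })
      vg <- array(0, d); vg[mask] <- vals$g
      vw <- array(0, d); vw[mask] <- vals$w
      gm[[s]] <- voxel_volume(vg, mask, atlas$voxel_size)
      wm[[s]] <- voxel_volume(vw, mask, atlas$voxel_size)
    }

    if ("bold" %in% modalities) {
      odd_r <- seq_len(atlas$R) %% 2 == 1
      kap <- pmin(pmax(noise$base_coherence +
                         so$coherence_add * odd_r + # regional site pattern
                         ifelse(seq_len(atlas$R) %in% aff & is_pat,
                                effects$coherence_shift, 0), 0.05), 0.95)
      gain <- rep(1, atlas$R)
      if (is_pat) gain[aff] <- gain[aff] * effects$amplitude_shift
      odd <- seq_len(atlas$R) %% 2 == 1
      gain[odd] <- gain[odd] * so$amp_gain_odd
      even <- !odd
      gain[even] <- gain[even] *
        exp(sl$bold_age * age_c + sl$bold_sex * male)
      L <- Sig[[meta$group[s]]][[meta$site[s]]]
      xb <- with_seed(child_seed(seed, 3L, s), {
        bl <- filtfilt(flt$b, flt$a, matrix(rnorm(T * atlas$R), T))
        bl <- scale(bl)
        ar <- matrix(rnorm(T * atlas$R), T)
        for (t in 2:T) ar[t, ] <- 0.3 * ar[t - 1, ] + ar[t, ]
        ar <- scale(ar)
        U <- sqrt(1 - noise$broadband_frac) * bl +
          sqrt(noise$broadband_frac) * ar
        Z <- U %*% L
        # voxel noise carries (mostly) the same band-limited spectrum as
        # the latents, so the shared-signal fraction keeps its meaning
        # after the cleaning bandpass instead of saturating toward 1
        E <- sqrt(0.85) * scale(filtfilt(flt$b, flt$a,
                                         matrix(rnorm(T * nvox), T))) +
          sqrt(0.15) * matrix(rnorm(T * nvox), T)
        X <- sqrt(kap[vox_lab])[col(E)] * Z[, vox_lab] +
          sqrt(1 - kap[vox_lab])[col(E)] * E
        100 + t(t(X) * gain[vox_lab])
      })
      arr <- array(0, c(d, T))
      flat <- matrix(arr, ncol = T)
      flat[as.vector(mask), ] <- t(xb)
      bold[[s]] <- bold_series(array(flat, c(d, T)), tr, mask)
      motion[[s]] <- with_seed(child_seed(seed, 4L, s), {
        m <- cbind(apply(matrix(rnorm(T * 3, 0, noise$motion_walk_trans),
                                T), 2, cumsum),
                   apply(matrix(rnorm(T * 3, 0, noise$motion_walk_rot),
                                T), 2, cumsum))
        spikes <- which(runif(T) < noise$motion_spike_prob)
        m[spikes, 1] <- m[spikes, 1] + noise$motion_spike_mm
        colnames(m) <- c("trans_x", "trans_y", "trans_z",
                         "rot_x", "rot_y", "rot_z")
        m
      })
    }
  }
  structure(list(meta = meta, gm = gm, wm = wm, bold = bold,
                 motion = motion, atlas = atlas,
                 truth = list(effects = effects, noise = noise, seed = seed,
                              T = T, tr = tr, age_group_shift =
                                age_group_shift, modalities = modalities)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d patients), %d site(s)\n",
              nrow(x$meta), sum(x$meta$group == "patient"),
              length(unique(x$meta$site))))
  invisible(x)
}
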