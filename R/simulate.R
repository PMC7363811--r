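#' Simulate motion-parameter traces
#'
#' Six-column random-walk traces (3 translations in mm, 3 rotations in
#' degrees), starting at zero, scaled so that typical excursions stay well
#' below the 3 mm / 3 degree QC limits. Motion never corrupts the volumes
#' themselves; it enters the BOLD model only as an optional confound
#' regressor, mirroring its role as a nuisance input.
#'
#' @param spec a `cohort_spec`.
#' @param subject integer subject index.
#' @return numeric matrix `n_timepoints x 6`, columns
#'   `trans_x/y/z`, `rot_x/y/z`.
#' @export
simulate_motion <- function(spec, subject) {
  set.seed(substream_seed(spec$seed, "motion", subject))
  n <- spec$n_timepoints
  step <- spec$motion_scale_mm / sqrt(n)
  tr <- vapply(1:3, function(i) cumsum(c(0, stats::rnorm(n - 1, 0, step))),
               numeric(n))
  ro <- vapply(1:3, function(i) cumsum(c(0, stats::rnorm(n - 1, 0, 0.5 * step))),
               numeric(n))
  m <- cbind(tr, ro)
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

# Fixed per-region sinusoid bank: frequencies drawn once per (cohort seed,
# region label) uniformly in the analysis band, shared by every subject, so
# between-subject amplitude differences reflect the implanted factors and
# not spectral sampling. Phases are drawn per subject.
region_freq_bank <- function(spec, label, f_lo = 0.01, f_hi = 0.08) {
  set.seed(substream_seed(spec$seed, "bank", label))
  stats::runif(spec$n_sinusoids, f_lo, f_hi)
}

# Shared low-frequency component from a fixed frequency bank with random
# phases, normalised so its variance is ~ amp^2 / 2 regardless of bank size.
lf_component <- function(n, tr_s, amp, freqs) {
  ph <- stats::runif(length(freqs), 0, 2 * pi)
  tt <- (seq_len(n) - 1) * tr_s
  amp * sqrt(2 / length(freqs)) * colSums(sin(outer(freqs, tt) * 2 * pi + ph))
}

# Effect multipliers for one subject's group: amplitude scale per region
# (alff/falff effects) and synchrony scale per region (reho effects).
effect_multipliers <- function(spec, group) {
  amp <- list(); rho <- list()
  for (eff in spec$effect_regions) {
    if (!group %in% eff$groups) next
    if (eff$metric %in% c("alff", "falff")) {
      amp[[eff$region]] <- (1 + eff$effect_size) *
        if (is.null(amp[[eff$region]])) 1 else amp[[eff$region]]
    } else {
      rho[[eff$region]] <- (1 + eff$effect_size) *
        if (is.null(rho[[eff$region]])) 1 else rho[[eff$region]]
    }
  }
  list(amp = amp, rho = rho)
}

#' Simulate one subject's BOLD series
#'
#' Each voxel's series is `baseline + sqrt(rho_r) * s_r(t) + noise`, where
#' `s_r` is the region's shared low-frequency component (a fixed bank of
#' sinusoids with frequencies drawn once per region per cohort, uniform in
#' 0.01–0.08 Hz, and per-subject random phases) and
#' the noise is white with sd `noise_sd`. Implanted ALFF/fALFF effects scale
#' the shared amplitude by `1 + effect_size` in affected groups; ReHo effects
#' scale the synchrony weight `rho_r` the same way (clamped below 1). A
#' linear drift and a motion-locked confound are added to every brain voxel;
#' both are removed by detrending / nuisance regression downstream.
#'
#' @param spec a `cohort_spec`.
#' @param template output of [make_template()].
#' @param subject integer subject index into [cohort_subjects()].
#' @param latents optional precomputed [cohort_latents()] matrix.
#' @return list with `bold` (a [bold_series()]) and `motion` (matrix).
#' @export
simulate_subject_bold <- function(spec, template, subject, latents = NULL) {
  subj <- cohort_subjects(spec)
  group <- as.character(subj$group[subject])
  if (is.null(latents)) latents <- cohort_latents(spec)
  for (eff in spec$effect_regions) {
    if (is.null(template$masks[[eff$region]])) {
      stop("effect region '", eff$region, "' not present in template", call. = FALSE)
    }
  }
  labs <- template$labels
  grid <- template$grid
  n <- spec$n_timepoints
  V <- prod(grid$shape)
  mult <- effect_multipliers(spec, group)
  motion <- simulate_motion(spec, subject)

  lab_vals <- sort(unique(labs[labs > 0L]))
  lab_names <- names(region_labels())[match(lab_vals, region_labels())]
  banks <- lapply(lab_vals, function(l) region_freq_bank(spec, l))
  set.seed(substream_seed(spec$seed, "bold", subject))
  x <- matrix(0, nrow = V, ncol = n)
  for (i in seq_along(lab_vals)) {
    idx <- which(labs == lab_vals[i])
    nm <- lab_names[i]
    amp <- spec$signal_amp
    if (!is.na(nm) && !is.null(mult$amp[[nm]])) amp <- amp * mult$amp[[nm]]
    if (!is.na(nm) && nm %in% colnames(latents) && spec$amp_cv > 0) {
      amp <- amp * exp(spec$amp_cv * latents[subject, nm] - spec$amp_cv^2 / 2)
    }
    rho <- spec$synchrony_rho
    if (!is.na(nm) && !is.null(mult$rho[[nm]])) rho <- min(rho * mult$rho[[nm]], 0.99)
    s_r <- lf_component(n, spec$tr_s, amp, banks[[i]])
    x[idx, ] <- rep(spec$baseline + sqrt(rho) * s_r, each = length(idx))
  }
  brain_idx <- which(template$masks$brain)
  x[brain_idx, ] <- x[brain_idx, ] +
    spec$noise_sd * matrix(stats::rnorm(length(brain_idx) * n), ncol = n)
  drift <- spec$drift_amp * seq(-0.5, 0.5, length.out = n)
  conf <- drift
  m1 <- motion[, 1]
  if (stats::sd(m1) > 0) {
    conf <- conf + spec$motion_confound_weight * (m1 - mean(m1)) / stats::sd(m1)
  }
  x[brain_idx, ] <- x[brain_idx, ] + rep(conf, each = length(brain_idx))
  bold <- bold_series(array(x, dim = c(grid$shape, n)), grid, spec$tr_s,
                      template$masks$brain)
  list(bold = bold, motion = motion)
}

#' Simulate BOLD series and motion traces for a set of subjects
#'
#' @inheritParams simulate_subject_bold
#' @param subjects integer subject indices (default: the whole cohort).
#' @return named list (by subject id) of [simulate_subject_bold()] outputs.
#' @export
simulate_bold <- function(spec, template, subjects = NULL) {
  subj <- cohort_subjects(spec)
  if (is.null(subjects)) subjects <- seq_len(nrow(subj))
  latents <- cohort_latents(spec)
  out <- lapply(subjects, function(s) {
    simulate_subject_bold(spec, template, s, latents)
  })
  names(out) <- subj$subject[subjects]
  out
}

#' Simulate DAT uptake volumes
#'
#' Occipital reference (and all other nonspecific brain) voxels get mean
#' uptake `dat_uref`; striatal voxels get `dat_uref` times the group binding
#' ratio of their subregion (most specific `dat_binding` key wins; voxels in
#' the anterior-putamen rule gap keep the parent putamen binding), with
#' per-subject lognormal jitter on the binding carrying the latent factors
#' that induce the requested cross-modal correlations; additive Gaussian
#' noise with sd `dat_noise_sd` is applied inside the brain.
#'
#' @inheritParams simulate_subject_bold
#' @param subjects integer subject indices (default: whole cohort).
#' @return named list of 3D uptake arrays.
#' @export
simulate_dat <- function(spec, template, subjects = NULL) {
  subj <- cohort_subjects(spec)
  if (is.null(subjects)) subjects <- seq_len(nrow(subj))
  latents <- cohort_latents(spec)
  parc <- parcellate_striatum(template$labels, template$grid)
  labs <- template$labels
  caud <- labs == 10L | labs == 11L
  puta <- labs == 12L | labs == 13L
  brain <- template$masks$brain
  out <- lapply(subjects, function(s) {
    group <- as.character(subj$group[s])
    binding <- array(0, dim = template$grid$shape)
    binding[brain] <- 1
    assign_bind <- function(mask, region) {
      key <- resolve_binding_key(spec, region, group)
      b <- resolve_binding(spec, region, group)
      if (b <= 0) stop("binding ratio must be positive for ", region, call. = FALSE)
      if (spec$binding_cv > 0 && key %in% colnames(latents)) {
        b <- b * exp(spec$binding_cv * latents[s, key] - spec$binding_cv^2 / 2)
      }
      binding[mask] <<- b
    }
    assign_bind(caud, "caudate")
    assign_bind(puta, "putamen")
    for (r in names(parc$masks)) {
      key <- resolve_binding_key(spec, r, group)
      if (key == r || length(spec$target_correlations) > 0) assign_bind(parc$masks[[r]], r)
    }
    set.seed(substream_seed(spec$seed, "dat", s))
    vol <- spec$dat_uref * binding
    if (spec$dat_noise_sd > 0) {
      vol[brain] <- vol[brain] + stats::rnorm(sum(brain), 0, spec$dat_noise_sd)
    }
    vol
  })
  names(out) <- subj$subject[subjects]
  out
}

# Key under which a region's binding (and its jitter latent) is resolved:
# the region's own name if the group's binding map defines it, else its
# parent structure.
resolve_binding_key <- function(spec, region, group) {
  b <- spec$dat_binding[[group]]
  if (!is.null(b) && region %in% names(b)) return(region)
  if (grepl("caudate", region)) "caudate" else
    if (grepl("putamen", region)) "putamen" else region
}

#' Synthetic gray-matter partial-volume-estimate map
#'
#' 1 inside gray-matter tissue (cortical GM, striatum, reference and effect
#' regions), 0 elsewhere, softened by a small Gaussian kernel so voxels at
#' tissue borders take intermediate values — enough structure for the
#' reference-mask PVE threshold to act on.
#'
#' @param template output of [make_template()].
#' @param fwhm_mm kernel width (default 3).
#' @return 3D numeric array in `[0, 1]`.
#' @export
make_gm_pve <- function(template, fwhm_mm = 3) {
  gm_labels <- c(1L, 10L, 11L, 12L, 13L, 20L, 30L, 31L, 32L)
  ind <- array(as.numeric(template$labels %in% gm_labels),
               dim = template$grid$shape)
  smooth_gaussian(ind, fwhm_mm, template$grid)
}

default_np_columns <- function() {
  c("digit_span_forward", "digit_span_backward", "stroop_color",
    "COWAT_animal", "COWAT_supermarket", "SVLT_free_recall",
    "RCFT_copy", "RCFT_immediate_recall", "K_BNT")
}

#' Generate covariate and neuropsychological score tables
#'
#' Emits the cohort's demographic/covariate table (group, age, sex,
#' education, MMSE, UPDRS left/right sums, scan-interval columns) and an NP
#' score table. Group means echo the published cohort's demography (patients
#' older-ish, DIP least educated, MMSE control > PD > DIP); NP columns named
#' in `target_correlations` are driven by the shared latent factors so the
#' requested correlations hold.
#'
#' @param spec a `cohort_spec`.
#' @param latents optional precomputed [cohort_latents()] matrix.
#' @return list with data.frames `covariates` and `np_scores`.
#' @export
make_tables <- function(spec, latents = NULL) {
  if (is.null(latents)) latents <- cohort_latents(spec)
  subj <- cohort_subjects(spec)
  n <- nrow(subj)
  g <- as.character(subj$group)
  set.seed(substream_seed(spec$seed, "tables"))
  pick <- function(vals) unname(vals[g])
  trunc_norm <- function(mu, sd, lo, hi) pmin(pmax(stats::rnorm(n, mu, sd), lo), hi)

  age <- round(trunc_norm(pick(c(pd = 69.7, dip = 69.9, control = 67.8)), 7.5, 40, 95), 1)
  sex <- stats::rbinom(n, 1, pick(c(pd = 0.324, dip = 0.217, control = 0.286)))
  education <- round(trunc_norm(pick(c(pd = 9.6, dip = 6.6, control = 11.0)), 5, 0, 22), 1)
  mmse <- round(trunc_norm(pick(c(pd = 26.6, dip = 23.7, control = 28.5)),
                           pick(c(pd = 2.3, dip = 4.8, control = 1.5)), 10, 30))
  updrs_right <- ifelse(g == "control", NA_real_,
                        pmax(round(stats::rnorm(n, 12, 4)), 0))
  asym <- ifelse(g == "pd", stats::rnorm(n, 2.5, 2.5),
                 ifelse(g == "dip", stats::rnorm(n, -0.5, 1.5), NA_real_))
  updrs_left <- pmax(round(updrs_right - asym), 0)
  mri_dat_interval_days <- round(abs(stats::rnorm(n, 25, 25)))
  mri_np_interval_days <- round(abs(stats::rnorm(n, 25, 25)))
  covariates <- data.frame(
    subject = subj$subject, group = g, age = age, sex = sex,
    education = education, mmse = mmse,
    updrs_right = updrs_right, updrs_left = updrs_left,
    mri_dat_interval_days = mri_dat_interval_days,
    mri_np_interval_days = mri_np_interval_days,
    stringsAsFactors = FALSE
  )

  np_mu <- c(digit_span_forward = 6, digit_span_backward = 4, stroop_color = 90,
             COWAT_animal = 14, COWAT_supermarket = 16, SVLT_free_recall = 17,
             RCFT_copy = 31, RCFT_immediate_recall = 13, K_BNT = 45)
  np_sd <- c(digit_span_forward = 1.2, digit_span_backward = 1.2, stroop_color = 18,
             COWAT_animal = 4, COWAT_supermarket = 5, SVLT_free_recall = 5,
             RCFT_copy = 4, RCFT_immediate_recall = 5, K_BNT = 8)
  patient_shift <- -0.5  # patients score ~half an sd lower
  np <- data.frame(subject = subj$subject, stringsAsFactors = FALSE)
  for (col in default_np_columns()) {
    z <- if (col %in% colnames(latents)) latents[, col] else stats::rnorm(n)
    shift <- ifelse(g == "control", 0, patient_shift)
    np[[col]] <- round(np_mu[[col]] + np_sd[[col]] * (z + shift), 1)
  }
  list(covariates = covariates, np_scores = np)
}
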