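#' Deterministic substream seeds
#'
#' One top-level cohort seed is expanded into per-stream, per-subject seeds
#' by a counter scheme, so that subject k's data are reproducible no matter
#' how many other subjects are generated, and the BOLD, motion, DAT, latent
#' and table streams never share draws.
#'
#' @param seed integer top-level seed.
#' @param stream one of `"latent"`, `"bold"`, `"motion"`, `"dat"`,
#'   `"tables"`, `"nullsim"`, `"bank"`.
#' @param index non-negative integer counter (e.g. subject index).
#' @return integer seed < 2^31.
#' @export
substream_seed <- function(seed, stream, index = 0L) {
  ids <- c(latent = 1, bold = 2, motion = 3, dat = 4, tables = 5, nullsim = 6,
           bank = 7)
  if (!stream %in% names(ids)) stop("unknown stream: ", stream, call. = FALSE)
  s <- as.double(seed) %% 2147483647
  v <- (s * 48271 + ids[[stream]] * 1664525 + as.double(index) * 22695477) %% 2147483629
  as.integer(v) + 1L
}

#' Synthetic cohort specification
#'
#' Collects every knob of the synthetic-cohort generator: group sizes, the
#' acquisition geometry (timepoints, TR), the implanted regional effects,
#' the shared-signal / noise model, the DAT binding ratios per group, and
#' the cross-modal correlations to induce. All randomness downstream flows
#' from `seed` via [substream_seed()].
#'
#' @param n_per_group named integer(3): subjects in the `pd`, `dip` and
#'   `control` groups. Defaults mirror the published cohort (68/69/70).
#' @param n_timepoints volumes acquired per subject (default 165, of which
#'   3 are discarded downstream).
#' @param tr_s repetition time in seconds (default 2).
#' @param effect_regions list of implanted group effects; each element is
#'   `list(region =, metric = "reho"|"alff"|"falff", groups =, effect_size =)`.
#'   ALFF/fALFF effects scale the shared-component amplitude by
#'   `1 + effect_size` in the affected groups; ReHo effects scale the
#'   within-region synchrony the same way (clamped below 1).
#' @param noise_sd standard deviation of idiosyncratic voxel noise (> 0).
#' @param synchrony_rho within-region signal-sharing weight in `[0, 1)`;
#'   the shared component enters each voxel with weight `sqrt(synchrony_rho)`.
#' @param dat_binding per-group named binding ratios. Keys may be parent
#'   labels (`caudate`, `putamen`) or subregion names
#'   (e.g. `posterior_putamen`), the most specific key winning.
#' @param target_correlations list of `list(a =, b =, rho =)` requests; `a`
#'   names a striatal binding source (e.g. `"caudate"`), `b` either an
#'   effect region (its per-subject amplitude factor) or an NP score column,
#'   and `rho` the target Pearson correlation, induced by sharing a latent
#'   subject factor.
#' @param seed integer top-level seed.
#' @param baseline,signal_amp,n_sinusoids BOLD signal model: constant
#'   baseline, shared-component amplitude (arbitrary BOLD units) and number
#'   of sinusoids in the fixed low-frequency bank.
#' @param motion_scale_mm scale of the random-walk motion traces.
#' @param motion_confound_weight,drift_amp amplitude of the motion-locked
#'   confound and linear drift added to every brain voxel.
#' @param dat_uref,dat_noise_sd mean reference-region uptake and additive
#'   Gaussian noise sd of the DAT volumes.
#' @param binding_cv,amp_cv between-subject coefficients of variation of the
#'   binding ratios and of the effect-region amplitude factors (lognormal
#'   jitter; the latent normal scores carry the induced correlations).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(pd = 68L, dip = 69L, control = 70L),
                        n_timepoints = 165L, tr_s = 2,
                        effect_regions = list(),
                        noise_sd = 0.5, synchrony_rho = 0.3,
                        dat_binding = default_dat_binding(),
                        target_correlations = list(),
                        seed = 1L,
                        baseline = 100, signal_amp = 1, n_sinusoids = 8L,
                        motion_scale_mm = 0.2,
                        motion_confound_weight = 0.1, drift_amp = 1,
                        dat_uref = 10, dat_noise_sd = 0.2,
                        binding_cv = 0.15, amp_cv = 0.2) {
  if (is.null(names(n_per_group))) names(n_per_group) <- c("pd", "dip", "control")
  stopifnot(length(n_per_group) == 3L, all(n_per_group >= 1L),
            setequal(names(n_per_group), c("pd", "dip", "control")))
  n_per_group <- as.integer(n_per_group[c("pd", "dip", "control")])
  names(n_per_group) <- c("pd", "dip", "control")
  stopifnot(n_timepoints >= 10L, tr_s > 0)
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("noise_sd must be positive", call. = FALSE)
  }
  if (synchrony_rho < 0 || synchrony_rho >= 1) {
    stop("synchrony_rho must lie in [0, 1)", call. = FALSE)
  }
  for (eff in effect_regions) {
    stopifnot(is.character(eff$region),
              eff$metric %in% c("reho", "alff", "falff"),
              all(eff$groups %in% c("pd", "dip")),
              is.numeric(eff$effect_size))
  }
  for (g in names(dat_binding)) {
    if (any(dat_binding[[g]] <= 0)) {
      stop("binding ratios must be positive (group ", g, ")", call. = FALSE)
    }
  }
  for (tc in target_correlations) {
    if (abs(tc$rho) >= 1) stop("target correlation |rho| must be < 1", call. = FALSE)
  }
  structure(
    list(n_per_group = n_per_group, n_timepoints = as.integer(n_timepoints),
         tr_s = tr_s, effect_regions = effect_regions, noise_sd = noise_sd,
         synchrony_rho = synchrony_rho, dat_binding = dat_binding,
         target_correlations = target_correlations, seed = as.integer(seed),
         baseline = baseline, signal_amp = signal_amp,
         n_sinusoids = as.integer(n_sinusoids),
         motion_scale_mm = motion_scale_mm,
         motion_confound_weight = motion_confound_weight, drift_amp = drift_amp,
         dat_uref = dat_uref, dat_noise_sd = dat_noise_sd,
         binding_cv = binding_cv, amp_cv = amp_cv),
    class = "cohort_spec"
  )
}

#' Default per-group striatal binding ratios
#'
#' Controls and DIP have normal presynaptic uptake; PD has reduced caudate
#' and putamen binding, most severe in the posterior putamen — the pattern
#' the diagnostic DAT criterion relies on.
#' @export
default_dat_binding <- function() {
  list(
    pd = c(caudate = 2.2, putamen = 2.4, posterior_putamen = 1.5),
    dip = c(caudate = 3.0, putamen = 3.0),
    control = c(caudate = 3.0, putamen = 3.0)
  )
}

#' Subject table for a cohort spec
#'
#' @param spec a `cohort_spec`.
#' @return data.frame with `subject` (zero-padded id) and `group`.
#' @export
cohort_subjects <- function(spec) {
  n <- sum(spec$n_per_group)
  data.frame(
    subject = sprintf("sub-%03d", seq_len(n)),
    group = factor(rep(names(spec$n_per_group), spec$n_per_group),
                   levels = c("pd", "dip", "control")),
    stringsAsFactors = FALSE
  )
}

# Names that may carry a latent subject factor: striatal binding sources,
# effect-region amplitude factors, and any NP columns named in targets.
latent_names <- function(spec) {
  striatal <- c("caudate", "putamen", "ventral_caudate", "dorsal_caudate",
                "posterior_putamen", "ventral_anterior_putamen",
                "dorsal_anterior_putamen")
  regions <- c("insula", "occipital_assoc", "cerebellum")
  np <- unlist(lapply(spec$target_correlations, function(tc) c(tc$a, tc$b)))
  unique(c(striatal, regions, np))
}

#' Per-subject latent factors implementing the requested correlations
#'
#' Every binding source, effect region and targeted NP column gets an i.i.d.
#' standard-normal latent per subject; each `target_correlations` entry then
#' replaces the latent of its `b` member by
#' `rho * latent_a + sqrt(1 - rho^2) * latent_b`, which induces the target
#' correlation between the quantities the two latents drive. Each `b` may
#' appear in at most one target.
#'
#' @param spec a `cohort_spec`.
#' @return numeric matrix, subjects x latent names.
#' @export
cohort_latents <- function(spec) {
  nms <- latent_names(spec)
  n <- sum(spec$n_per_group)
  set.seed(substream_seed(spec$seed, "latent"))
  L <- matrix(stats::rnorm(n * length(nms)), nrow = n,
              dimnames = list(NULL, nms))
  bs <- vapply(spec$target_correlations, function(tc) tc$b, character(1))
  if (anyDuplicated(bs)) {
    stop("each target-correlation 'b' member may appear only once", call. = FALSE)
  }
  for (tc in spec$target_correlations) {
    L[, tc$b] <- tc$rho * L[, tc$a] + sqrt(1 - tc$rho^2) * L[, tc$b]
  }
  L
}

#' Resolve the binding ratio of a striatal subregion for one group
#'
#' The most specific key present in `spec$dat_binding[[group]]` wins:
#' a subregion key (e.g. `posterior_putamen`), else its parent
#' (`caudate`/`putamen`), else 1 (nonspecific).
#' @param spec a `cohort_spec`.
#' @param region subregion or parent name.
#' @param group `"pd"`, `"dip"` or `"control"`.
#' @export
resolve_binding <- function(spec, region, group) {
  b <- spec$dat_binding[[group]]
  if (!is.null(b) && region %in% names(b)) return(unname(b[region]))
  parent <- if (grepl("caudate", region)) "caudate" else
    if (grepl("putamen", region)) "putamen" else region
  if (!is.null(b) && parent %in% names(b)) return(unname(b[parent]))
  1
}
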