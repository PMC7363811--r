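#!/usr/bin/env Rscript
# Stage 2 — branch preprocessing and voxel-wise metric maps for one subject.
#
# The ReHo branch is detrend -> band-pass (0.01-0.08 Hz) -> nuisance
# regression and stays unsmoothed; the ALFF/fALFF branch is detrend ->
# nuisance regression -> 4-mm smoothing, with the frequency band applied
# inside the metric. Writes the three raw and normalised maps plus a QC
# record for the first PD subject.

suppressMessages(library(restmap))

out <- "results/metrics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- cohort_spec(
  n_per_group = c(pd = 15, dip = 15, control = 15),
  effect_regions = list(list(region = "insula", metric = "alff",
                             groups = c("pd", "dip"), effect_size = -0.5)),
  target_correlations = list(list(a = "caudate", b = "insula", rho = 0.5)),
  seed = 1
)
tpl <- make_template()
config <- default_run_config()

sb <- simulate_subject_bold(spec, tpl, 1)
series <- discard_initial(sb$bold, config$n_discard)
cat("Subject sub-001:", dim(sb$bold$data)[4], "volumes acquired,",
    dim(series$data)[4], "retained after discarding\n")

s_reho <- preprocess_branch(series, sb$motion, tpl$masks, "reho",
                            config$f_lo, config$f_hi, config$fwhm_mm)
s_alff <- preprocess_branch(series, sb$motion, tpl$masks, "alff",
                            config$f_lo, config$f_hi, config$fwhm_mm)

reho <- reho_map(s_reho, config$neighborhood, config$k_min)
alff <- alff_map(s_alff, config$f_lo, config$f_hi)
falff <- falff_map(s_alff, config$f_lo, config$f_hi)

for (m in list(reho, alff, falff)) {
  write_nifti(m$data, tpl$grid,
              file.path(out, sprintf("sub-001_%s_raw.nii.gz", m$metric)))
  gm <- normalize_map(m, "global_mean_divided")
  write_nifti(gm$data, tpl$grid,
              file.path(out, sprintf("sub-001_%s_gmdiv.nii.gz", m$metric)))
  write_nifti(normalize_map(m, "zscore")$data, tpl$grid,
              file.path(out, sprintf("sub-001_%s_zscore.nii.gz", m$metric)))
  cat(sprintf("%-6s in-mask mean %.4g (normalised map mean %.4g)\n",
              m$metric, mean(m$data[m$mask]), mean(gm$data[gm$mask])))
}
jsonlite::write_json(
  list(subject = "sub-001", band = c(config$f_lo, config$f_hi),
       neighborhood = config$neighborhood,
       degenerate_reho_voxels = reho$qc$degenerate_voxels,
       degenerate_falff_voxels = falff$qc$degenerate_voxels),
  file.path(out, "sub-001_qc.json"), auto_unbox = TRUE, pretty = TRUE)
cat("Maps and QC written to", out, "\n")
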