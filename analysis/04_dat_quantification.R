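#!/usr/bin/env Rscript
# Stage 4 — striatal parcellation and DAT binding-ratio quantification.
#
# The caudate is split at z = 0 and the putamen at y = 0; the anterior
# putamen is split at z = -4 / z = 0, leaving the (-4, 0] gap unassigned as
# the rules dictate. Every voxel is normalised by the mean uptake of the
# occipital GM reference (PVE > 0.9) and averaged per subregion.

suppressMessages(library(restmap))

out <- "results/dat"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- cohort_spec(
  n_per_group = c(pd = 15, dip = 15, control = 15),
  effect_regions = list(list(region = "insula", metric = "alff",
                             groups = c("pd", "dip"), effect_size = -0.5)),
  target_correlations = list(list(a = "caudate", b = "insula", rho = 0.5)),
  seed = 1
)
tpl <- make_template()

parc <- parcellate_striatum(tpl$labels, tpl$grid)
cat("Subregion voxel counts:\n")
print(vapply(parc$masks, sum, numeric(1)))
cat("Anterior-putamen rule-gap voxels (unassigned):",
    parc$provenance$anterior_putamen_gap_voxels, "\n")

lab <- array(0L, dim = tpl$grid$shape)
for (i in seq_along(parc$masks)) lab[parc$masks[[i]]] <- i
write_nifti(array(as.numeric(lab), dim = tpl$grid$shape), tpl$grid,
            file.path(out, "striatal_subregions.nii.gz"))

tab <- snbr_table(simulate_dat(spec, tpl), tpl, gm_pve = make_gm_pve(tpl),
                  pve_threshold = 0.9)
utils::write.csv(tab, file.path(out, "snbr.csv"), row.names = FALSE)
grp <- cohort_subjects(spec)$group
cat("\nGroup-mean SNBR per subregion:\n")
cols <- names(parc$masks)
summ <- t(vapply(levels(grp), function(g) {
  colMeans(tab[grp == g, cols])
}, numeric(length(cols))))
print(round(summ, 3))
utils::write.csv(data.frame(group = rownames(summ), round(summ, 4)),
                 file.path(out, "snbr_group_means.csv"), row.names = FALSE)
cat("The PD posterior putamen sits near the generator's implanted 1.5",
    "against 3.0 in DIP/controls.\n")
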