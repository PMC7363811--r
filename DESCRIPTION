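Package: restmap
Title: Resting-State fMRI Regional Metrics, Cluster-Corrected Group Maps and
    Striatal DAT Quantification on Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale re-implementation of a resting-state fMRI analysis
    chain for parkinsonism studies: temporal preprocessing (volume discarding,
    motion quality control, linear detrending, ideal band-pass filtering,
    nuisance regression, Gaussian smoothing), voxel-wise regional homogeneity
    (Kendall's coefficient of concordance), amplitude of low-frequency
    fluctuation (ALFF) and fractional ALFF maps, covariate-adjusted group
    contrasts with Monte-Carlo cluster-extent correction and conjunction of
    two patient-versus-control results, coordinate-rule parcellation of the
    striatum with specific-to-nonspecific binding-ratio quantification of
    dopamine-transporter volumes, and sphere-ROI Pearson correlation tables.
    A synthetic-cohort generator with known ground truth (implanted regional
    effects, binding ratios and cross-modal correlations) makes every stage
    verifiable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
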