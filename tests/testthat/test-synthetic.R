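test_that("identical cohort specs reproduce bit-identical outputs", {
  tpl <- small_template()
  spec1 <- cohort_spec(n_per_group = c(pd = 2, dip = 2, control = 2),
                       n_timepoints = 40, seed = 42)
  spec2 <- cohort_spec(n_per_group = c(pd = 2, dip = 2, control = 2),
                       n_timepoints = 40, seed = 42)
  a <- simulate_subject_bold(spec1, tpl, 3)
  b <- simulate_subject_bold(spec2, tpl, 3)
  expect_identical(a$bold$data, b$bold$data)
  expect_identical(a$motion, b$motion)
  expect_identical(simulate_dat(spec1, tpl, 2), simulate_dat(spec2, tpl, 2))
  expect_identical(make_tables(spec1), make_tables(spec2))
  # per-subject reproducibility is independent of which subjects are generated
  expect_identical(simulate_bold(spec1, tpl, c(1, 3))[[2]]$bold$data,
                   a$bold$data)
})

test_that("near-unit synchrony with vanishing noise gives interior ReHo of 1", {
  tpl <- sync_template()
  spec <- cohort_spec(n_per_group = c(pd = 1, dip = 1, control = 1),
                      n_timepoints = 40, noise_sd = 1e-10, amp_cv = 0,
                      synchrony_rho = 0.99, motion_confound_weight = 0,
                      drift_amp = 0, seed = 5)
  sb <- simulate_subject_bold(spec, tpl, 1)
  rh <- reho_map(sb$bold, 27, k_min = 14)
  interior <- region_interior(tpl$masks$insula)
  expect_gt(sum(interior), 0)
  expect_true(all(abs(rh$data[interior] - 1) < 1e-12))
})

test_that("doubling the shared amplitude doubles interior band ALFF", {
  tpl <- small_template()
  base <- list(n_per_group = c(pd = 1, dip = 1, control = 1),
               n_timepoints = 64, noise_sd = 1e-12, synchrony_rho = 0.5,
               motion_confound_weight = 0, drift_amp = 0, seed = 9)
  s1 <- do.call(cohort_spec, c(base, list(signal_amp = 1)))
  s2 <- do.call(cohort_spec, c(base, list(signal_amp = 2)))
  a1 <- alff_map(detrend_linear(simulate_subject_bold(s1, tpl, 1)$bold))
  a2 <- alff_map(detrend_linear(simulate_subject_bold(s2, tpl, 1)$bold))
  m <- tpl$masks$occipital_ref
  expect_equal(a2$data[m], 2 * a1$data[m], tolerance = 1e-8)
})

test_that("with zero effects, group differences in region ALFF are only noise", {
  tpl <- small_template()
  m <- tpl$masks$occipital_ref
  pvals <- numeric(60)
  for (r in seq_len(60)) {
    spec <- cohort_spec(n_per_group = c(pd = 5, dip = 1, control = 5),
                        n_timepoints = 40, seed = 1000 + r, amp_cv = 0)
    sims <- simulate_bold(spec, tpl)
    grp <- cohort_subjects(spec)$group
    vals <- vapply(sims, function(s) {
      mean(alff_map(detrend_linear(s$bold))$data[m])
    }, numeric(1))
    pvals[r] <- stats::t.test(vals[grp == "pd"], vals[grp == "control"])$p.value
  }
  # at alpha = 0.01 nearly all replicates should be non-significant
  expect_gte(mean(pvals > 0.01), 0.93)
})

test_that("noise-free DAT phantoms hit the requested binding exactly", {
  tpl <- small_template()
  spec <- cohort_spec(n_per_group = c(pd = 1, dip = 1, control = 1),
                      dat_binding = list(pd = c(caudate = 2, posterior_putamen = 1.5,
                                                putamen = 2.4),
                                         dip = c(caudate = 3, putamen = 3),
                                         control = c(caudate = 3, putamen = 3)),
                      dat_noise_sd = 0, binding_cv = 0, seed = 3)
  vols <- simulate_dat(spec, tpl)
  tab <- snbr_table(vols, tpl)
  expect_equal(tab$posterior_putamen, c(1.5, 3, 3))
  expect_equal(tab$ventral_caudate, c(2, 3, 3))
  expect_equal(tab$dorsal_anterior_putamen, c(2.4, 3, 3))
  # uniform binding of 1 everywhere -> SNBR identically 1
  spec1 <- cohort_spec(n_per_group = c(pd = 1, dip = 1, control = 1),
                       dat_binding = list(pd = c(caudate = 1, putamen = 1),
                                          dip = c(caudate = 1, putamen = 1),
                                          control = c(caudate = 1, putamen = 1)),
                       dat_noise_sd = 0, binding_cv = 0, seed = 3)
  tab1 <- snbr_table(simulate_dat(spec1, tpl), tpl)
  for (col in c("ventral_caudate", "dorsal_caudate", "posterior_putamen",
                "ventral_anterior_putamen", "dorsal_anterior_putamen")) {
    expect_equal(tab1[[col]], rep(1, 3))
  }
})

test_that("a requested binding/NP correlation is realised in the sample", {
  spec <- cohort_spec(n_per_group = c(pd = 60, dip = 1, control = 1),
                      target_correlations = list(
                        list(a = "caudate", b = "COWAT_supermarket", rho = 0.5)),
                      seed = 21)
  lat <- cohort_latents(spec)
  tabs <- make_tables(spec, lat)
  pd <- cohort_subjects(spec)$group == "pd"
  # binding is lognormal in the caudate latent; correlate on that scale
  binding <- exp(spec$binding_cv * lat[pd, "caudate"])
  r <- stats::cor(binding, tabs$np_scores$COWAT_supermarket[pd])
  ci <- fisher_ci(0.5, sum(pd))
  expect_gt(r, ci[1])
  expect_lt(r, ci[2])
})

test_that("cohort tables have the demographic shape of the study design", {
  spec <- cohort_spec(seed = 2)  # default 68/69/70
  tabs <- make_tables(spec)
  expect_identical(nrow(tabs$covariates), 207L)
  expect_identical(nrow(tabs$np_scores), 207L)
  expect_true(all(tabs$covariates$group %in% c("pd", "dip", "control")))
  expect_true(all(is.na(tabs$covariates$updrs_right[tabs$covariates$group == "control"])))
  # all-zero intervals pass the downstream filter untouched
  cv <- tabs$covariates
  cv$mri_dat_interval_days <- 0
  expect_identical(nrow(interval_filter(cv, "mri_dat_interval_days")$included),
                   nrow(cv))
  # a subject drawn with right-left difference > 2 is classified asymmetric
  d <- cv$updrs_right - cv$updrs_left
  big <- which(!is.na(d) & d > 2)
  skip_if(length(big) == 0)
  expect_true(all(asymmetry_class(cv$updrs_right[big], cv$updrs_left[big]) ==
                    "asymmetric_right"))
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd")
  expect_error(cohort_spec(synchrony_rho = 1), "synchrony_rho")
  expect_error(cohort_spec(dat_binding = list(pd = c(caudate = -1))), "positive")
  expect_error(cohort_spec(target_correlations = list(list(a = "caudate",
                                                           b = "K_BNT", rho = 1))),
               "rho")
  tpl <- small_template()
  spec <- cohort_spec(n_per_group = c(pd = 1, dip = 1, control = 1),
                      effect_regions = list(list(region = "cerebellum",
                                                 metric = "alff",
                                                 groups = "pd", effect_size = 1)))
  expect_error(simulate_subject_bold(spec, tpl, 1), "cerebellum")
})
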