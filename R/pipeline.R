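#' Rebuild template masks from a label volume
#'
#' Inverse of the label encoding of [make_template()]: used when a cohort is
#' loaded from disk rather than generated in memory.
#'
#' @param labels integer 3D label array.
#' @param grid the `template_grid`.
#' @return list with `labels`, `masks`, `grid` as from [make_template()].
#' @export
template_from_labels <- function(labels, grid) {
  labels <- array(as.integer(round(labels)), dim = grid$shape)
  codes <- region_labels()
  masks <- list(brain = labels > 0L, gm = labels == codes[["gm"]],
                wm = labels == codes[["wm"]], csf = labels == codes[["csf"]])
  for (nm in setdiff(names(codes), c("gm", "wm", "csf"))) {
    masks[[nm]] <- labels == codes[[nm]]
  }
  list(labels = labels, masks = masks, grid = grid)
}

subject_inputs <- function(spec, template, s, latents, cohort_dir, subj) {
  id <- subj$subject[s]
  if (is.null(cohort_dir)) {
    return(simulate_subject_bold(spec, template, s, latents))
  }
  bold_path <- file.path(cohort_dir, paste0(id, "_bold.nii.gz"))
  motion_path <- file.path(cohort_dir, paste0(id, "_motion.txt"))
  if (!file.exists(bold_path)) {
    stop("preprocess stage: BOLD file missing for subject ", id, call. = FALSE)
  }
  if (!file.exists(motion_path)) {
    stop("preprocess stage: motion file missing for subject ", id, call. = FALSE)
  }
  nb <- read_nifti(bold_path)
  list(bold = bold_series(nb$data, nb$grid, spec$tr_s, template$masks$brain),
       motion = as.matrix(utils::read.table(motion_path)))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Sequences every stage end to end: per-subject simulation (or loading
#' from a [write_cohort()] directory), volume discarding, motion QC, the
#' branch preprocessing, ReHo/ALFF/fALFF maps with global-mean and z-score
#' normalisation, the Monte-Carlo extent threshold, covariate-adjusted
#' PD-vs-control and DIP-vs-control contrasts with cluster-extent
#' correction, their conjunction, DAT SNBR quantification, sphere-ROI
#' extraction at the conjunction peaks, and the interval-filtered Pearson
#' correlation tables against striatal SNBR and NP scores. Identical
#' (spec, config) reproduce identical outputs.
#'
#' @param spec a `cohort_spec`.
#' @param template output of [make_template()]; defaults to the standard
#'   template on the default grid.
#' @param config a `run_config`.
#' @param metrics subset of `c("reho", "alff", "falff")` to compute.
#' @param out_dir optional directory for TSV/CSV/JSON outputs.
#' @param cohort_dir optional directory written by [write_cohort()]; if
#'   given, BOLD/motion/DAT inputs are read from disk instead of simulated.
#' @param k_crit optional named list with precomputed extent thresholds
#'   (`smoothed`, `unsmoothed`) to skip the Monte-Carlo stage.
#' @return list with `k_crit`, `contrasts`, `conjunctions`,
#'   `conjunction_tables`, `snbr`, `roi_means`, `correlations_dat`,
#'   `correlations_np`, `qc`, `tables`, `design`, `template`, `config`.
#' @export
run_pipeline <- function(spec, template = NULL, config = default_run_config(),
                         metrics = c("reho", "alff", "falff"), out_dir = NULL,
                         cohort_dir = NULL, k_crit = NULL) {
  validate_run_config(config)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (is.null(template)) {
    template <- if (is.null(cohort_dir)) make_template() else {
      lab <- read_nifti(file.path(cohort_dir, "labels.nii.gz"))
      template_from_labels(lab$data, lab$grid)
    }
  }
  grid <- template$grid
  subj <- cohort_subjects(spec)
  latents <- cohort_latents(spec)
  tables <- make_tables(spec, latents)
  n <- nrow(subj)
  V <- prod(grid$shape)

  gmd <- list(); zsc <- list()
  for (m in metrics) { gmd[[m]] <- matrix(0, V, n); zsc[[m]] <- matrix(0, V, n) }
  qc <- data.frame(subject = subj$subject, motion_pass = NA,
                   degenerate_reho = NA_integer_, stringsAsFactors = FALSE)
  for (s in seq_len(n)) {
    inp <- tryCatch(
      subject_inputs(spec, template, s, latents, cohort_dir, subj),
      error = function(e) stop("subject ", subj$subject[s], ": ",
                               conditionMessage(e), call. = FALSE))
    mq <- motion_qc(inp$motion, config$max_mm, config$max_deg)
    qc$motion_pass[s] <- mq$pass
    series <- discard_initial(inp$bold, config$n_discard)
    if ("reho" %in% metrics) {
      sr <- preprocess_branch(series, inp$motion, template$masks, "reho",
                              config$f_lo, config$f_hi, config$fwhm_mm,
                              config$order)
      mp <- reho_map(sr, config$neighborhood, config$k_min)
      qc$degenerate_reho[s] <- mp$qc$degenerate_voxels
      gmd$reho[, s] <- as.numeric(normalize_map(mp, "global_mean_divided")$data)
      zsc$reho[, s] <- as.numeric(normalize_map(mp, "zscore")$data)
    }
    if (any(c("alff", "falff") %in% metrics)) {
      sa <- preprocess_branch(series, inp$motion, template$masks, "alff",
                              config$f_lo, config$f_hi, config$fwhm_mm,
                              config$order)
      if ("alff" %in% metrics) {
        mp <- alff_map(sa, config$f_lo, config$f_hi)
        gmd$alff[, s] <- as.numeric(normalize_map(mp, "global_mean_divided")$data)
        zsc$alff[, s] <- as.numeric(normalize_map(mp, "zscore")$data)
      }
      if ("falff" %in% metrics) {
        mp <- falff_map(sa, config$f_lo, config$f_hi)
        gmd$falff[, s] <- as.numeric(normalize_map(mp, "global_mean_divided")$data)
        zsc$falff[, s] <- as.numeric(normalize_map(mp, "zscore")$data)
      }
    }
  }
  keep <- which(qc$motion_pass)

  if (is.null(k_crit)) {
    k_crit <- list()
    if (any(c("alff", "falff") %in% metrics)) {
      k_crit$smoothed <- cluster_extent_threshold(
        template$masks$brain, grid, config$fwhm_mm, config$p_voxel,
        config$alpha, config$n_iter,
        seed = substream_seed(config$seed, "nullsim", 1L),
        connectivity = config$connectivity)$k_crit
    }
    if ("reho" %in% metrics) {
      k_crit$unsmoothed <- cluster_extent_threshold(
        template$masks$brain, grid, 0, config$p_voxel, config$alpha,
        config$n_iter, seed = substream_seed(config$seed, "nullsim", 2L),
        connectivity = config$connectivity)$k_crit
    }
  }
  metric_k <- function(m) if (m == "reho") k_crit$unsmoothed else k_crit$smoothed

  design <- merge(subj, tables$covariates[c("subject", "age", "sex",
                                            "education", "mmse")],
                  by = "subject", sort = FALSE)
  design <- design[match(subj$subject, design$subject), ]
  contrast_pairs <- list(pd_control = c("pd", "control"),
                         dip_control = c("dip", "control"))
  contrasts <- list(); conjunctions <- list(); conj_tables <- list()
  for (m in metrics) {
    res <- list()
    for (cn in names(contrast_pairs)) {
      ct <- voxelwise_contrast(gmd[[m]][, keep, drop = FALSE],
                               design[keep, , drop = FALSE],
                               contrast_pairs[[cn]], template$masks$brain, grid)
      res[[cn]] <- apply_cluster_threshold(ct, config$p_voxel, metric_k(m),
                                           config$connectivity)
    }
    contrasts[[m]] <- res
    conjunctions[[m]] <- conjunction(res$pd_control, res$dip_control,
                                     config$connectivity)
    tb <- conjunctions[[m]]$clusters
    if (nrow(tb)) tb <- cbind(metric = m, tb)
    conj_tables[[m]] <- tb
  }

  dat <- if (is.null(cohort_dir)) simulate_dat(spec, template) else {
    out <- lapply(subj$subject, function(id) {
      p <- file.path(cohort_dir, paste0(id, "_dat.nii.gz"))
      if (!file.exists(p)) stop("dat stage: DAT file missing for subject ",
                                id, call. = FALSE)
      read_nifti(p)$data
    })
    names(out) <- subj$subject
    out
  }
  pve <- make_gm_pve(template)
  snbr <- snbr_table(dat, template, gm_pve = pve,
                     pve_threshold = config$pve_threshold)

  rois <- list()
  for (m in metrics) {
    tb <- conjunctions[[m]]$clusters
    for (i in seq_len(nrow(tb))) {
      rois[[sprintf("%s_cluster%d", m, tb$label[i])]] <- sphere_members(
        c(tb$peak_x_mm[i], tb$peak_y_mm[i], tb$peak_z_mm[i]),
        config$roi_radius_mm, grid, template$masks$brain)
    }
  }
  roi_means <- NULL; cor_dat <- NULL; cor_np <- NULL
  if (length(rois)) {
    roi_metric <- sub("_cluster[0-9]+$", "", names(rois))
    roi_means <- data.frame(subject = subj$subject, stringsAsFactors = FALSE)
    for (i in seq_along(rois)) {
      vals <- colMeans(zsc[[roi_metric[i]]][rois[[i]]$voxels, , drop = FALSE])
      roi_means[[names(rois)[i]]] <- vals
    }
    pd_ids <- subj$subject[subj$group == "pd" & qc$motion_pass]
    dat_keep <- interval_filter(tables$covariates, "mri_dat_interval_days",
                                config$max_interval_days)$included
    pd_dat <- intersect(pd_ids, dat_keep$subject)
    sn_cols <- c("subject", "ventral_caudate", "dorsal_caudate",
                 "posterior_putamen", "ventral_anterior_putamen",
                 "dorsal_anterior_putamen")
    if (length(pd_dat) >= 3L) {
      cor_dat <- pearson_table(
        roi_means[roi_means$subject %in% pd_dat, , drop = FALSE],
        snbr[snbr$subject %in% pd_dat, sn_cols, drop = FALSE])
    }
    pat_ids <- subj$subject[subj$group %in% c("pd", "dip") & qc$motion_pass]
    np_keep <- interval_filter(tables$covariates, "mri_np_interval_days",
                               config$max_interval_days)$included
    pat_np <- intersect(pat_ids, np_keep$subject)
    if (length(pat_np) >= 3L) {
      cor_np <- pearson_table(
        roi_means[roi_means$subject %in% pat_np, , drop = FALSE],
        tables$np_scores[tables$np_scores$subject %in% pat_np, , drop = FALSE])
    }
  }

  result <- list(k_crit = k_crit, contrasts = contrasts,
                 conjunctions = conjunctions,
                 conjunction_tables = do.call(rbind, conj_tables),
                 snbr = snbr, rois = rois, roi_means = roi_means,
                 correlations_dat = cor_dat, correlations_np = cor_np,
                 qc = qc, tables = tables, design = design,
                 template = template, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir, spec)
  result
}

write_pipeline_outputs <- function(result, out_dir, spec) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.table(x, p, sep = "\t", row.names = FALSE, quote = FALSE)
    p
  }
  paths <- character()
  if (!is.null(result$conjunction_tables) && nrow(result$conjunction_tables)) {
    paths <- c(paths, wt(result$conjunction_tables, "conjunction_clusters.tsv"))
  }
  for (m in names(result$contrasts)) {
    for (cn in names(result$contrasts[[m]])) {
      tb <- result$contrasts[[m]][[cn]]$clusters
      if (nrow(tb)) paths <- c(paths, wt(tb, sprintf("clusters_%s_%s.tsv", m, cn)))
    }
  }
  paths <- c(paths, wt(result$snbr, "snbr.tsv"))
  if (!is.null(result$roi_means)) paths <- c(paths, wt(result$roi_means, "roi_means.tsv"))
  if (!is.null(result$correlations_dat)) {
    paths <- c(paths, wt(result$correlations_dat, "correlations_dat.tsv"))
  }
  if (!is.null(result$correlations_np)) {
    paths <- c(paths, wt(result$correlations_np, "correlations_np.tsv"))
  }
  paths <- c(paths, wt(result$qc, "qc.tsv"))
  prov <- list(
    config = unclass(result$config),
    k_crit = result$k_crit,
    n_per_group = as.list(spec$n_per_group),
    seed = spec$seed,
    outputs = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
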