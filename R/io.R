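#' Read a NIfTI-1 volume and its grid
#'
#' The affine must be axis-aligned with positive diagonal (canonical
#' right/anterior/superior order); anything else is an error naming the
#' offending axes — reorientation is out of scope because every synthetic
#' volume is generated in the template orientation.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @return list with `data` (3D or 4D array) and `grid` (`template_grid`).
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  bad <- which(diag(rot) <= 0 | colSums(abs(offdiag)) > 1e-4 * max(abs(diag(rot))))
  if (length(bad)) {
    stop("affine is not in canonical R/A/S diagonal form on axis(es): ",
         paste(c("x", "y", "z")[bad], collapse = ", "), call. = FALSE)
  }
  d <- dim(img)
  grid <- template_grid(d[1:3], diag(rot), aff[1:3, 4])
  list(data = array(as.numeric(img), dim = d), grid = grid)
}

#' Write a volume as NIfTI-1
#'
#' @param volume 3D or 4D numeric array.
#' @param grid the `template_grid` defining the affine.
#' @param path output path (.nii or .nii.gz).
#' @param tr_s optional repetition time stored in the time pixdim.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, grid, path, tr_s = NULL) {
  stopifnot(all(dim(volume)[1:3] == grid$shape))
  aff <- diag(c(grid$voxel_size_mm, 1))
  aff[1:3, 4] <- grid$origin_mm
  pix <- c(1, grid$voxel_size_mm, if (is.null(tr_s)) 1 else tr_s, 0, 0, 0)
  img <- RNifti::asNifti(volume, reference = list(pixdim = pix),
                         datatype = "double")
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Default run configuration
#'
#' All defaults equal the study's stated analysis settings: band 0.01–0.08
#' Hz, 4-mm FWHM smoothing (ALFF branch), 27-voxel ReHo neighbourhood,
#' voxel p 0.005 two-tailed, corrected alpha 0.05/3, 3 mm / 3 degree motion
#' limits, 3 discarded volumes, 61-day interval limit.
#' @return named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    f_lo = 0.01, f_hi = 0.08, fwhm_mm = 4, neighborhood = 27L, k_min = 14L,
    p_voxel = 0.005, alpha = 0.05 / 3, n_iter = 2000L, connectivity = 26L,
    max_mm = 3, max_deg = 3, n_discard = 3L, max_interval_days = 61,
    roi_radius_mm = 4, pve_threshold = 0.9, order = "metric", seed = 1L
  ), class = "run_config")
}

validate_run_config <- function(config) {
  stopifnot(
    config$f_lo >= 0, config$f_lo < config$f_hi,
    config$fwhm_mm >= 0, config$neighborhood %in% c(7L, 19L, 27L),
    config$p_voxel > 0, config$p_voxel < 1, config$alpha > 0, config$alpha < 1,
    config$n_iter >= 1L, config$connectivity %in% c(6L, 18L, 26L),
    config$max_mm > 0, config$max_deg > 0, config$n_discard >= 0L,
    config$max_interval_days >= 0, config$roi_radius_mm >= 0,
    config$pve_threshold >= 0, config$pve_threshold <= 1,
    config$order %in% c("metric", "literal")
  )
  invisible(config)
}

#' Load / save a run configuration (YAML)
#'
#' Unknown keys are rejected; missing keys take their defaults; the loaded
#' configuration is validated. `save_run_config` followed by
#' `load_run_config` reproduces the configuration.
#'
#' @param path YAML file.
#' @return a validated `run_config`.
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  config <- default_run_config()
  unknown <- setdiff(names(vals), names(config))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(vals)) {
    config[[k]] <- if (is.integer(config[[k]])) as.integer(vals[[k]]) else vals[[k]]
  }
  validate_run_config(config)
  config
}

#' @rdname load_run_config
#' @param config a `run_config`.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12L)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Emits per-subject BOLD volumes (.nii.gz), 6-column whitespace-delimited
#' motion files, DAT volumes, the template label volume and GM PVE map,
#' covariate and NP CSV tables, and a JSON manifest listing every path, its
#' md5 hash, and the generating `cohort_spec`.
#'
#' @param spec a `cohort_spec`.
#' @param template output of [make_template()].
#' @param dir output directory (created if needed).
#' @param subjects integer subject indices (default: whole cohort).
#' @return path of the manifest file, invisibly.
#' @export
write_cohort <- function(spec, template, dir, subjects = NULL) {
  subj <- cohort_subjects(spec)
  if (is.null(subjects)) subjects <- seq_len(nrow(subj))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- template$grid
  latents <- cohort_latents(spec)
  files <- list()
  write_nifti(array(as.numeric(template$labels), dim = grid$shape),
              grid, file.path(dir, "labels.nii.gz"))
  files$labels <- "labels.nii.gz"
  write_nifti(make_gm_pve(template), grid, file.path(dir, "gm_pve.nii.gz"))
  files$gm_pve <- "gm_pve.nii.gz"
  dat <- simulate_dat(spec, template, subjects)
  for (i in seq_along(subjects)) {
    id <- subj$subject[subjects[i]]
    sb <- simulate_subject_bold(spec, template, subjects[i], latents)
    write_nifti(sb$bold$data, grid, file.path(dir, paste0(id, "_bold.nii.gz")),
                tr_s = spec$tr_s)
    utils::write.table(sb$motion, file.path(dir, paste0(id, "_motion.txt")),
                       row.names = FALSE, col.names = FALSE)
    write_nifti(dat[[id]], grid, file.path(dir, paste0(id, "_dat.nii.gz")))
    files[[paste0(id, "_bold")]] <- paste0(id, "_bold.nii.gz")
    files[[paste0(id, "_motion")]] <- paste0(id, "_motion.txt")
    files[[paste0(id, "_dat")]] <- paste0(id, "_dat.nii.gz")
  }
  tables <- make_tables(spec, latents)
  utils::write.csv(tables$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(tables$np_scores, file.path(dir, "np_scores.csv"),
                   row.names = FALSE)
  files$covariates <- "covariates.csv"
  files$np_scores <- "np_scores.csv"
  hashes <- as.list(tools::md5sum(file.path(dir, unlist(files))))
  names(hashes) <- unlist(files)
  manifest <- list(
    subjects = subj$subject[subjects],
    groups = as.character(subj$group[subjects]),
    files = files, md5 = hashes,
    spec = unclass(spec)[setdiff(names(unclass(spec)), c("effect_regions",
                                                         "dat_binding",
                                                         "target_correlations"))],
    effect_regions = spec$effect_regions,
    dat_binding = spec$dat_binding,
    target_correlations = spec$target_correlations
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}
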