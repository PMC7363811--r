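#' Parcellate the striatum by template-coordinate rules
#'
#' Splits the caudate and putamen labels into five subregions on voxel-centre
#' mm coordinates, with boundary inclusivity exactly as the rules state:
#' caudate into ventral (z <= 0) and dorsal (z > 0); putamen into posterior
#' (y <= 0) and anterior (y > 0); and the anterior putamen into ventral
#' (z <= -4) and dorsal (z > 0). Anterior-putamen voxels with -4 < z <= 0
#' are covered by neither anterior rule: they are left unassigned and their
#' count reported in the provenance rather than guessing an intended rule.
#' Left and right hemispheres are pooled by default.
#'
#' @param labels integer 3D label array (caudate 10/11, putamen 12/13).
#' @param grid the `template_grid` whose affine defines mm coordinates.
#' @param per_hemisphere if TRUE, emit `_l`/`_r` masks instead of pooled.
#' @return object of class `striatal_parcellation`: `masks` (named list of
#'   logical arrays: `ventral_caudate`, `dorsal_caudate`,
#'   `posterior_putamen`, `ventral_anterior_putamen`,
#'   `dorsal_anterior_putamen`), and `provenance` (source labels, rules,
#'   anterior-putamen gap voxel count).
#' @export
parcellate_striatum <- function(labels, grid, per_hemisphere = FALSE) {
  caud <- labels == 10L | labels == 11L
  puta <- labels == 12L | labels == 13L
  if (!any(caud)) stop("caudate labels (10/11) missing", call. = FALSE)
  if (!any(puta)) stop("putamen labels (12/13) missing", call. = FALSE)
  co <- grid_coord_arrays(grid)
  build <- function(caud, puta, suffix = "") {
    anterior <- puta & co$y > 0
    m <- list(
      ventral_caudate = caud & co$z <= 0,
      dorsal_caudate = caud & co$z > 0,
      posterior_putamen = puta & co$y <= 0,
      ventral_anterior_putamen = anterior & co$z <= -4,
      dorsal_anterior_putamen = anterior & co$z > 0
    )
    gap <- anterior & co$z > -4 & co$z <= 0
    if (nzchar(suffix)) names(m) <- paste0(names(m), suffix)
    list(masks = m, gap = sum(gap))
  }
  if (per_hemisphere) {
    l <- build(labels == 10L, labels == 12L, "_l")
    r <- build(labels == 11L, labels == 13L, "_r")
    masks <- c(l$masks, r$masks)
    gap <- l$gap + r$gap
  } else {
    b <- build(caud, puta)
    masks <- b$masks
    gap <- b$gap
  }
  empty <- names(masks)[!vapply(masks, any, logical(1))]
  if (length(empty)) {
    warning("empty striatal subregion(s): ", paste(empty, collapse = ", "))
  }
  structure(
    list(masks = masks, grid = grid,
         provenance = list(
           source_labels = c(caudate = "10/11", putamen = "12/13"),
           rules = c(caudate = "ventral z<=0 / dorsal z>0",
                     putamen = "posterior y<=0 / anterior y>0",
                     anterior_putamen = "ventral z<=-4 / dorsal z>0 (gap -4<z<=0 unassigned)"),
           anterior_putamen_gap_voxels = gap)),
    class = "striatal_parcellation"
  )
}

#' Specific-to-nonspecific binding-ratio volume
#'
#' Divides every voxel of a DAT uptake volume by the scalar mean uptake of
#' the occipital gray-matter reference region; if a GM partial-volume map is
#' supplied, the reference is first restricted to voxels whose PVE exceeds
#' the threshold (default 0.9).
#'
#' @param dat 3D uptake array.
#' @param occipital_gm logical reference-region mask.
#' @param gm_pve optional GM PVE array in `[0, 1]`.
#' @param pve_threshold reference PVE threshold (default 0.9).
#' @return list with `snbr` (3D array), `reference_mean`,
#'   `reference_voxels`.
#' @export
snbr_volume <- function(dat, occipital_gm, gm_pve = NULL, pve_threshold = 0.9) {
  ref <- occipital_gm
  if (!is.null(gm_pve)) ref <- ref & gm_pve > pve_threshold
  n_ref <- sum(ref)
  if (n_ref == 0L) stop("reference region empty after PVE thresholding", call. = FALSE)
  mu <- mean(dat[ref])
  if (mu <= 0) stop("reference mean uptake is not positive", call. = FALSE)
  list(snbr = dat / mu, reference_mean = mu, reference_voxels = n_ref)
}

#' Regional mean SNBR for one subject
#'
#' Arithmetic mean of the SNBR volume over each striatal subregion mask;
#' empty regions yield NA with a warning.
#'
#' @param snbr 3D SNBR array (from [snbr_volume()]).
#' @param parcellation a `striatal_parcellation` on the same grid.
#' @param grid the grid `snbr` lives on (checked against the parcellation).
#' @return one-row data.frame: one column per subregion plus `_n` voxel
#'   counts.
#' @export
regional_snbr <- function(snbr, parcellation, grid = parcellation$grid) {
  stop_if_grid_mismatch(grid, parcellation$grid, "SNBR volume and parcellation")
  out <- list()
  for (nm in names(parcellation$masks)) {
    m <- parcellation$masks[[nm]]
    if (!any(m)) {
      warning("empty subregion: ", nm)
      out[[nm]] <- NA_real_
    } else {
      out[[nm]] <- mean(snbr[m])
    }
    out[[paste0(nm, "_n")]] <- sum(m)
  }
  as.data.frame(out)
}

#' Cohort SNBR table
#'
#' Runs [snbr_volume()] and [regional_snbr()] for every subject's DAT
#' volume.
#'
#' @param dat_volumes named list of 3D uptake arrays (by subject id).
#' @param template output of [make_template()] (supplies the occipital
#'   reference mask and labels).
#' @param gm_pve,pve_threshold passed to [snbr_volume()].
#' @param per_hemisphere passed to [parcellate_striatum()].
#' @return data.frame, one row per subject: `subject`, subregion means,
#'   voxel counts, `reference_mean`.
#' @export
snbr_table <- function(dat_volumes, template, gm_pve = NULL, pve_threshold = 0.9,
                       per_hemisphere = FALSE) {
  parc <- parcellate_striatum(template$labels, template$grid, per_hemisphere)
  rows <- lapply(names(dat_volumes), function(id) {
    sv <- snbr_volume(dat_volumes[[id]], template$masks$occipital_ref,
                      gm_pve, pve_threshold)
    cbind(data.frame(subject = id, stringsAsFactors = FALSE),
          regional_snbr(sv$snbr, parc),
          data.frame(reference_mean = sv$reference_mean))
  })
  do.call(rbind, rows)
}

#' Dice overlap coefficient between two masks
#'
#' `2 |A & B| / (|A| + |B|)`; 0 if both masks are empty.
#' @param a,b logical arrays of equal dimension.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(0)
  2 * sum(a & b) / denom
}
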