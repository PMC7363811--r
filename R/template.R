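#' Region label codes used by the synthetic template
#'
#' Integer codes for the label volume emitted by [make_template()]. Gray
#' matter is the background tissue inside the brain mask; the striatal,
#' reference and effect regions are carved out of it.
#' @export
region_labels <- function() {
  c(
    gm = 1L, wm = 2L, csf = 3L,
    caudate_l = 10L, caudate_r = 11L,
    putamen_l = 12L, putamen_r = 13L,
    occipital_ref = 20L,
    insula = 30L, occipital_assoc = 31L, cerebellum = 32L
  )
}

#' Default synthetic region layout
#'
#' Boxes (in template mm coordinates) for ventricular CSF, deep WM, left and
#' right caudate and putamen, an occipital gray-matter reference region, and
#' three effect regions standing in for the insular, occipital-association
#' and cerebellar sites where patient-versus-control changes are implanted.
#' The caudate boxes straddle the z = 0 plane and the putamen boxes straddle
#' both the y = 0 plane and the z = -4 plane, so every striatal subregion of
#' the coordinate-rule parcellation is nonempty on the default grid.
#'
#' @param grid a `template_grid`; used only to scale the brain ellipsoid.
#' @return named list of region specs (`label`, `center_mm`, `half_mm`).
#' @export
default_region_layout <- function(grid = default_grid()) {
  list(
    csf = list(label = 3L, center_mm = c(0, 0, 9), half_mm = c(4, 8, 2)),
    wm = list(label = 2L, center_mm = c(0, 0, 21), half_mm = c(10, 12, 4)),
    caudate_l = list(label = 10L, center_mm = c(-12, 9, 0), half_mm = c(4, 7, 7)),
    caudate_r = list(label = 11L, center_mm = c(12, 9, 0), half_mm = c(4, 7, 7)),
    putamen_l = list(label = 12L, center_mm = c(-21, -1.5, -3), half_mm = c(4, 10.5, 7.5)),
    putamen_r = list(label = 13L, center_mm = c(21, -1.5, -3), half_mm = c(4, 10.5, 7.5)),
    occipital_ref = list(label = 20L, center_mm = c(0, -33, 0), half_mm = c(10, 5, 6)),
    insula = list(label = 30L, center_mm = c(30, 3, 3), half_mm = c(4, 6, 6)),
    occipital_assoc = list(label = 31L, center_mm = c(15, -27, 6), half_mm = c(5, 5, 5)),
    cerebellum = list(label = 32L, center_mm = c(3, -18, -18), half_mm = c(7, 6, 6))
  )
}

box_mask <- function(grid, center_mm, half_mm) {
  co <- grid_coord_arrays(grid)
  abs(co$x - center_mm[1]) <= half_mm[1] &
    abs(co$y - center_mm[2]) <= half_mm[2] &
    abs(co$z - center_mm[3]) <= half_mm[3]
}

ellipsoid_mask <- function(grid, center_mm, radii_mm) {
  co <- grid_coord_arrays(grid)
  ((co$x - center_mm[1]) / radii_mm[1])^2 +
    ((co$y - center_mm[2]) / radii_mm[2])^2 +
    ((co$z - center_mm[3]) / radii_mm[3])^2 <= 1
}

#' Build the synthetic template: label volume and tissue masks
#'
#' Constructs a deterministic integer label volume on `grid`: an ellipsoidal
#' brain mask filled with gray matter, into which the regions of
#' `region_layout` are carved as disjoint integer labels. Serves the role a
#' maximum-probability atlas plays for real data: it supplies the whole-brain
#' mask, GM/WM/CSF masks, the striatal labels the parcellation rules split,
#' the occipital GM reference for binding-ratio normalisation, and the named
#' effect regions the generator implants signals into.
#'
#' @param grid a `template_grid`.
#' @param region_layout named list of region specs as produced by
#'   [default_region_layout()].
#' @return list with `labels` (integer 3D array), `masks` (named list of
#'   logical arrays: `brain`, `gm`, `wm`, `csf`, plus one per layout region)
#'   and `grid`.
#' @details Overlapping regions are an error naming the colliding labels.
#'   A caudate or putamen lying entirely on one side of its split plane
#'   (z = 0 for the caudate, y = 0 for the putamen) triggers a warning,
#'   because the corresponding subregion would be empty.
#' @export
make_template <- function(grid = default_grid(), region_layout = default_region_layout(grid)) {
  brain <- ellipsoid_mask(grid, c(0, 0, 0),
                          grid$voxel_size_mm * (grid$shape - 1) / 2 + grid$voxel_size_mm / 2)
  labels <- array(0L, dim = grid$shape)
  labels[brain] <- 1L  # gray matter background
  placed <- list()
  for (nm in names(region_layout)) {
    spec <- region_layout[[nm]]
    m <- box_mask(grid, spec$center_mm, spec$half_mm) & brain
    hit <- labels > 1L & m
    if (any(hit)) {
      offenders <- sort(unique(labels[hit]))
      prev <- names(placed)[vapply(placed, function(l) l %in% offenders, logical(1))]
      stop(sprintf("region '%s' overlaps already-placed region(s): %s",
                   nm, paste(prev, collapse = ", ")), call. = FALSE)
    }
    labels[m] <- spec$label
    placed[[nm]] <- spec$label
  }
  co <- grid_coord_arrays(grid)
  for (side in c("caudate_l", "caudate_r")) {
    if (!is.null(placed[[side]])) {
      m <- labels == placed[[side]]
      if (any(m) && all(co$z[m] > 0)) {
        warning(sprintf("ventral caudate empty: all %s voxels have z > 0", side))
      }
      if (any(m) && all(co$z[m] <= 0)) {
        warning(sprintf("dorsal caudate empty: all %s voxels have z <= 0", side))
      }
    }
  }
  for (side in c("putamen_l", "putamen_r")) {
    if (!is.null(placed[[side]])) {
      m <- labels == placed[[side]]
      if (any(m) && all(co$y[m] > 0)) {
        warning(sprintf("posterior putamen empty: all %s voxels have y > 0", side))
      }
      if (any(m) && all(co$y[m] <= 0)) {
        warning(sprintf("anterior putamen empty: all %s voxels have y <= 0", side))
      }
    }
  }
  masks <- list(brain = brain, gm = labels == 1L, wm = labels == 2L, csf = labels == 3L)
  for (nm in names(region_layout)) {
    masks[[nm]] <- labels == region_layout[[nm]]$label
  }
  list(labels = labels, masks = masks, grid = grid)
}
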