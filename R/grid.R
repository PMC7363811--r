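#' Template grid geometry
#'
#' A `template_grid` fixes the common voxel grid every volume in a cohort
#' lives on: the number of voxels per axis, the isotropic-or-not voxel size
#' in mm, and the mm coordinate of the first voxel centre. Axes are oriented
#' right/anterior/superior-positive, so template coordinates in mm (the ones
#' the striatal split rules and sphere ROIs use) are defined by an invertible
#' affine map from voxel indices.
#'
#' @param shape integer(3), voxels per axis (x, y, z).
#' @param voxel_size_mm numeric(3) or scalar, voxel edge length in mm.
#' @param origin_mm numeric(3), mm coordinate of the centre of voxel (1,1,1).
#'   Default centres the grid so that 0 mm lies on a voxel centre of every
#'   axis.
#' @return An object of class `template_grid`.
#' @export
template_grid <- function(shape, voxel_size_mm = 3, origin_mm = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  stopifnot(all(voxel_size_mm > 0))
  if (is.null(origin_mm)) {
    origin_mm <- -voxel_size_mm * (shape %/% 2L)
  }
  origin_mm <- rep_len(as.numeric(origin_mm), 3L)
  structure(
    list(shape = shape, voxel_size_mm = voxel_size_mm, origin_mm = origin_mm),
    class = "template_grid"
  )
}

#' Default desk-scale grid
#'
#' 24 x 28 x 24 voxels at 3 mm isotropic — small enough that the full
#' pipeline runs in minutes while preserving all mm-coordinate logic
#' (split planes at z = 0, z = -4 and y = 0 fall inside the striatal boxes).
#' @return A `template_grid`.
#' @export
default_grid <- function() template_grid(c(24L, 28L, 24L), 3)

#' @export
print.template_grid <- function(x, ...) {
  cat(sprintf(
    "<template_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, origin (%g, %g, %g) mm\n",
    x$shape[1], x$shape[2], x$shape[3],
    x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
    x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]
  ))
  invisible(x)
}

#' Voxel-index to mm-coordinate mapping
#'
#' @param grid a `template_grid`.
#' @param ijk integer matrix (n x 3) of 1-based voxel indices.
#' @return numeric matrix (n x 3) of voxel-centre mm coordinates.
#' @export
vox_to_mm <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  sweep(sweep(ijk - 1, 2L, grid$voxel_size_mm, `*`), 2L, grid$origin_mm, `+`)
}

#' @rdname vox_to_mm
#' @param mm numeric matrix (n x 3) of mm coordinates.
#' @return `mm_to_vox`: numeric matrix of fractional 1-based voxel indices.
#' @export
mm_to_vox <- function(grid, mm) {
  mm <- matrix(as.numeric(mm), ncol = 3L)
  sweep(sweep(mm, 2L, grid$origin_mm, `-`), 2L, grid$voxel_size_mm, `/`) + 1
}

#' mm coordinates of every voxel centre, one axis at a time
#'
#' @param grid a `template_grid`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of length `shape[axis]`.
#' @export
axis_coords_mm <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 1) * grid$voxel_size_mm[axis]
}

#' Coordinate arrays for the full grid
#'
#' Returns three 3D arrays giving the x, y, z mm coordinate of each voxel
#' centre. Used by the parcellation rules and sphere ROIs.
#' @param grid a `template_grid`.
#' @return list of arrays `x`, `y`, `z`, each of dim `grid$shape`.
#' @export
grid_coord_arrays <- function(grid) {
  sh <- grid$shape
  cx <- axis_coords_mm(grid, 1)
  cy <- axis_coords_mm(grid, 2)
  cz <- axis_coords_mm(grid, 3)
  list(
    x = array(rep(cx, times = sh[2] * sh[3]), dim = sh),
    y = array(rep(rep(cy, each = sh[1]), times = sh[3]), dim = sh),
    z = array(rep(cz, each = sh[1] * sh[2]), dim = sh)
  )
}

#' @rdname vox_to_mm
#' @param other a second `template_grid`.
#' @return `grids_equal`: logical.
#' @export
grids_equal <- function(grid, other, tol = 1e-6) {
  identical(grid$shape, other$shape) &&
    all(abs(grid$voxel_size_mm - other$voxel_size_mm) < tol) &&
    all(abs(grid$origin_mm - other$origin_mm) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!grids_equal(a, b)) {
    stop(sprintf("grid mismatch between %s: shapes/affines differ", what),
         call. = FALSE)
  }
  invisible(TRUE)
}
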