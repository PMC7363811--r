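#' Sphere ROI membership
#'
#' All voxels whose centre lies within `radius_mm` (Euclidean, inclusive)
#' of `center_mm`, optionally intersected with a brain mask. On a 3-mm grid
#' a 4-mm sphere centred on a voxel centre holds exactly 7 voxels: the
#' centre and its 6 face neighbours (edge neighbours sit at 3*sqrt(2) ~
#' 4.24 mm). `radius_mm = 0` selects the single nearest voxel.
#'
#' @param center_mm numeric(3) mm coordinates (must lie inside the grid).
#' @param radius_mm sphere radius in mm (default 4).
#' @param grid the `template_grid`.
#' @param mask optional logical array to intersect with.
#' @return object of class `sphere_roi`: `center_mm`, `radius_mm`,
#'   `voxels` (linear indices), `mask` (logical array).
#' @export
sphere_members <- function(center_mm, radius_mm = 4, grid, mask = NULL) {
  stopifnot(radius_mm >= 0)
  frac <- mm_to_vox(grid, matrix(center_mm, 1))
  if (any(frac < 0.5) || any(frac > grid$shape + 0.5)) {
    stop("sphere centre lies outside the grid", call. = FALSE)
  }
  co <- grid_coord_arrays(grid)
  d2 <- (co$x - center_mm[1])^2 + (co$y - center_mm[2])^2 + (co$z - center_mm[3])^2
  if (radius_mm == 0) {
    m <- array(FALSE, dim = grid$shape)
    m[which.min(d2)] <- TRUE
  } else {
    m <- d2 <= radius_mm^2
  }
  if (!is.null(mask)) m <- m & mask
  if (!any(m)) stop("sphere ROI is empty after masking", call. = FALSE)
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 voxels = which(m), mask = m, grid = grid),
            class = "sphere_roi")
}

#' Extract per-subject ROI means from metric maps
#'
#' Mean of each subject's (typically z-scored) metric map over each ROI's
#' member voxels.
#'
#' @param maps named list (by subject id) of `metric_map`s, or a voxels x
#'   subjects matrix.
#' @param rois named list of `sphere_roi`s (or logical arrays).
#' @param grid grid of the maps (checked against each `sphere_roi`).
#' @return data.frame: `subject` plus one column per ROI.
#' @export
extract_roi_means <- function(maps, rois, grid = NULL) {
  if (is.list(maps) && inherits(maps[[1]], "metric_map")) {
    ids <- names(maps)
    get_vec <- function(i) as.numeric(maps[[i]]$data)
    n <- length(maps)
  } else {
    ids <- colnames(maps) %||% sprintf("sub-%03d", seq_len(ncol(maps)))
    get_vec <- function(i) maps[, i]
    n <- ncol(maps)
  }
  roi_idx <- lapply(rois, function(r) {
    if (inherits(r, "sphere_roi")) {
      if (!is.null(grid)) stop_if_grid_mismatch(grid, r$grid, "maps and ROI")
      r$voxels
    } else {
      which(r)
    }
  })
  out <- data.frame(subject = ids, stringsAsFactors = FALSE)
  for (nm in names(rois)) out[[nm]] <- NA_real_
  for (i in seq_len(n)) {
    v <- get_vec(i)
    for (nm in names(rois)) out[[nm]][i] <- mean(v[roi_idx[[nm]]])
  }
  out
}

#' Filter subjects by scan interval
#'
#' Keeps rows whose interval column is at most `max_days` (default 61 days,
#' the fixed reading of "2 months or less"); both partitions are returned so
#' included-versus-excluded comparisons can be run.
#'
#' @param table data.frame with the interval column.
#' @param interval_col column name holding days between scans.
#' @param max_days inclusion limit in days (default 61).
#' @return list with `included`, `excluded` (data.frames) and
#'   `excluded_ids`.
#' @export
interval_filter <- function(table, interval_col, max_days = 61) {
  if (!interval_col %in% names(table)) {
    stop("missing interval column: ", interval_col, call. = FALSE)
  }
  iv <- table[[interval_col]]
  if (!all(is.finite(iv))) stop("interval column must be finite", call. = FALSE)
  keep <- iv <= max_days
  list(included = table[keep, , drop = FALSE],
       excluded = table[!keep, , drop = FALSE],
       excluded_ids = table$subject[!keep])
}

#' Pairwise Pearson correlation table
#'
#' Pearson r with two-tailed P for every (column of `x_table`) x (column of
#' `y_table`) pair, after listwise deletion of missing values within each
#' pair. Significance is flagged at P < 0.05 and P < 0.01 (uncorrected,
#' two-tailed); a Benjamini-Hochberg adjusted column is emitted as
#' supplementary output but not used for flagging. Zero-variance pairs are
#' marked undefined.
#'
#' @param x_table,y_table data.frames of numeric columns (a `subject`
#'   column, if present, is used to align rows and then dropped).
#' @return data.frame: `x`, `y`, `n`, `r`, `p`, `flag` (`""`, `"*"`,
#'   `"**"`), `p_bh`, `undefined`.
#' @export
pearson_table <- function(x_table, y_table) {
  align <- function(a, b) {
    if (!is.null(a$subject) && !is.null(b$subject)) {
      common <- intersect(a$subject, b$subject)
      a <- a[match(common, a$subject), , drop = FALSE]
      b <- b[match(common, b$subject), , drop = FALSE]
    }
    list(a = a[setdiff(names(a), "subject")], b = b[setdiff(names(b), "subject")])
  }
  al <- align(x_table, y_table)
  rows <- list()
  for (xn in names(al$a)) for (yn in names(al$b)) {
    x <- al$a[[xn]]; y <- al$b[[yn]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3L) stop("fewer than 3 complete pairs for ", xn, " vs ", yn, call. = FALSE)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        x = xn, y = yn, n = n, r = NA_real_, p = NA_real_, flag = "",
        undefined = TRUE, stringsAsFactors = FALSE)
    } else {
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                            alternative = "two.sided")
      rows[[length(rows) + 1L]] <- data.frame(
        x = xn, y = yn, n = n, r = unname(ct$estimate), p = ct$p.value,
        flag = if (ct$p.value < 0.01) "**" else if (ct$p.value < 0.05) "*" else "",
        undefined = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Classify motor-symptom asymmetry from UPDRS side sums
#'
#' Asymmetric iff the right-left difference is more than two points
#' (strictly: a difference of exactly 2 is symmetric), on the side of the
#' larger score. Vectorised.
#'
#' @param updrs_right,updrs_left non-negative side sums.
#' @return character vector: `"asymmetric_right"`, `"asymmetric_left"` or
#'   `"symmetric"`.
#' @export
asymmetry_class <- function(updrs_right, updrs_left) {
  if (any(updrs_right < 0, na.rm = TRUE) || any(updrs_left < 0, na.rm = TRUE)) {
    stop("UPDRS scores must be non-negative", call. = FALSE)
  }
  d <- updrs_right - updrs_left
  ifelse(is.na(d), NA_character_,
         ifelse(d > 2, "asymmetric_right",
                ifelse(d < -2, "asymmetric_left", "symmetric")))
}
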