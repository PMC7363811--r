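#' Voxel-wise covariate-adjusted two-group contrast
#'
#' For every in-mask voxel, an OLS fit of
#' `metric ~ intercept + group + age + sex + education + mmse` on the
#' subjects of the two contrasted groups; returns the t statistic of the
#' group coefficient (sign: first group minus second) and the residual
#' degrees of freedom. This is the pairwise-t-with-nuisance-covariates model
#' ("ANOVA contrast"): no variance pooling across a third group.
#'
#' @param maps numeric matrix, voxels x subjects (normalised metric values),
#'   or list of `metric_map`s.
#' @param design data.frame with columns `group` plus the covariates;
#'   one row per column of `maps`.
#' @param groups character(2), the two group labels (A, B); t > 0 means
#'   A > B.
#' @param mask logical 3D array (common analysis mask).
#' @param grid the `template_grid`.
#' @param covariates covariate column names (default age, sex, education,
#'   mmse).
#' @return list with `t` (3D array, 0 outside mask), `df`, `mask`, `grid`.
#' @export
voxelwise_contrast <- function(maps, design, groups, mask, grid,
                               covariates = c("age", "sex", "education", "mmse")) {
  if (is.list(maps) && inherits(maps[[1]], "metric_map")) {
    maps <- vapply(maps, function(m) as.numeric(m$data), numeric(prod(grid$shape)))
  }
  stopifnot(ncol(maps) == nrow(design), length(groups) == 2L)
  sel <- design$group %in% groups
  if (sum(design$group == groups[1]) < 2L || sum(design$group == groups[2]) < 2L) {
    stop("need at least 2 subjects per contrasted group", call. = FALSE)
  }
  d <- design[sel, , drop = FALSE]
  if (!all(vapply(d[covariates], function(v) all(is.finite(v)), logical(1)))) {
    stop("covariates must be finite", call. = FALSE)
  }
  X <- cbind(intercept = 1,
             group = as.numeric(d$group == groups[1]),
             as.matrix(d[covariates]))
  if (nrow(X) < ncol(X) + 2L) {
    stop("too few subjects for the covariate model", call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  Y <- t(maps[, sel, drop = FALSE])        # subjects x voxels
  df <- nrow(X) - ncol(X)
  XtXinv <- solve(crossprod(X))
  beta <- XtXinv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / df
  se <- sqrt(XtXinv[2, 2] * sigma2)
  tval <- ifelse(se > 0, beta[2, ] / se, 0)
  tval[!mask] <- 0
  list(t = array(tval, dim = grid$shape), df = df, mask = mask, grid = grid)
}

connectivity_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
  w <- rowSums(abs(off))
  switch(as.character(connectivity),
         "6" = off[w == 1L, , drop = FALSE],
         "18" = off[w <= 2L, , drop = FALSE],
         "26" = off,
         stop("connectivity must be 6, 18 or 26", call. = FALSE))
}

#' Label connected components of a logical 3D volume
#'
#' Components under face (6), face+edge (18) or face+edge+corner (26)
#' connectivity, via a voxel-adjacency graph.
#'
#' @param vol logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return integer array; 0 background, components numbered from 1 in
#'   decreasing size order.
#' @export
label_clusters <- function(vol, connectivity = 26L) {
  sh <- dim(vol)
  idx <- which(vol)
  lab <- array(0L, dim = sh)
  if (length(idx) == 0L) return(lab)
  off <- connectivity_offsets(connectivity)
  ijk <- arrayInd(idx, sh)
  inset <- logical(prod(sh)); inset[idx] <- TRUE
  pos <- integer(prod(sh)); pos[idx] <- seq_along(idx)
  edges <- NULL
  for (o in seq_len(nrow(off))) {
    ni <- ijk[, 1] + off[o, 1]; nj <- ijk[, 2] + off[o, 2]; nk <- ijk[, 3] + off[o, 3]
    ok <- ni >= 1L & ni <= sh[1] & nj >= 1L & nj <= sh[2] & nk >= 1L & nk <= sh[3]
    lin <- ni[ok] + (nj[ok] - 1L) * sh[1] + (nk[ok] - 1L) * sh[1] * sh[2]
    hit <- inset[lin]
    if (any(hit)) {
      edges <- rbind(edges, cbind(pos[idx[ok][hit]], pos[lin[hit]]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  ord <- order(as.integer(sizes), decreasing = TRUE)
  relabel <- integer(length(sizes)); relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  lab[idx] <- relabel[comp]
  lab
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates `n_iter` Gaussian white-noise volumes on the mask grid, smooths
#' each to `fwhm_mm`, standardises within the mask, thresholds two-tailed at
#' `p_voxel`, and records the maximum same-sign cluster size. The extent
#' threshold `k_crit` is the smallest cluster size k with empirical
#' `P(max cluster >= k) <= alpha`. This is the same construction the AFNI
#' cluster-simulation tool uses; the extent threshold is always recomputed
#' for the current mask and smoothness rather than reusing a value derived
#' for another grid.
#'
#' @param mask logical 3D array.
#' @param grid the `template_grid`.
#' @param fwhm_mm assumed smoothness of the noise (the applied kernel FWHM
#'   by default in the pipeline).
#' @param p_voxel two-tailed voxel-wise p threshold (default 0.005).
#' @param alpha corrected family-wise alpha (default 0.05/3, the
#'   Bonferroni-adjusted level for three pairwise comparisons).
#' @param n_iter Monte-Carlo iterations (>= 1000 recommended).
#' @param seed integer seed.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return list with `k_crit`, `max_sizes` (the simulated null maxima) and
#'   the parameters used.
#' @export
cluster_extent_threshold <- function(mask, grid, fwhm_mm, p_voxel = 0.005,
                                     alpha = 0.05 / 3, n_iter = 2000L,
                                     seed = 1L, connectivity = 26L) {
  stopifnot(p_voxel > 0, p_voxel < 1, alpha > 0, alpha <= 1)
  if (alpha < 1 / n_iter) {
    stop(sprintf("alpha = %g is below the 1/n_iter = %g resolution; increase n_iter",
                 alpha, 1 / n_iter), call. = FALSE)
  }
  set.seed(seed)
  zc <- stats::qnorm(1 - p_voxel / 2)
  nin <- sum(mask)
  max_sizes <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    noise <- array(stats::rnorm(prod(grid$shape)), dim = grid$shape)
    if (fwhm_mm > 0) noise <- smooth_gaussian(noise, fwhm_mm, grid)
    v <- noise[mask]
    z <- (v - mean(v)) / stats::sd(v)
    zvol <- array(0, dim = grid$shape)
    zvol[mask] <- z
    mx <- 0L
    for (sgn in c(1, -1)) {
      supra <- (sgn * zvol) > zc & mask
      if (any(supra)) {
        lab <- label_clusters(supra, connectivity)
        mx <- max(mx, max(tabulate(lab[lab > 0L])))
      }
    }
    max_sizes[it] <- mx
  }
  k <- 1L
  while (mean(max_sizes >= k) > alpha) k <- k + 1L
  list(k_crit = k, max_sizes = max_sizes,
       params = list(fwhm_mm = fwhm_mm, p_voxel = p_voxel, alpha = alpha,
                     n_iter = n_iter, seed = seed, connectivity = connectivity,
                     n_mask_voxels = nin))
}

#' Apply voxel and cluster-extent thresholds to a t map
#'
#' Two-tailed voxel threshold at `p_voxel` (on the t distribution with the
#' contrast's residual df), connected components computed separately for
#' positive and negative suprathreshold voxels under the configured
#' connectivity, and components smaller than `k_crit` removed. Peaks are
#' reported in template mm coordinates.
#'
#' @param contrast output of [voxelwise_contrast()] (fields `t`, `df`,
#'   `mask`, `grid`).
#' @param p_voxel two-tailed voxel p threshold (default 0.005).
#' @param k_crit cluster-extent threshold in voxels.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return object of class `cluster_result`: `t` volume, `labels` (integer
#'   array, clusters numbered across both signs), `clusters` (data.frame:
#'   label, size, peak mm coordinates, peak t, sign), and the thresholds
#'   used.
#' @export
apply_cluster_threshold <- function(contrast, p_voxel = 0.005, k_crit,
                                    connectivity = 26L) {
  tvol <- contrast$t
  if (!all(is.finite(tvol[contrast$mask]))) {
    stop("t volume contains non-finite values inside the mask", call. = FALSE)
  }
  tc <- stats::qt(1 - p_voxel / 2, df = contrast$df)
  labels <- array(0L, dim = dim(tvol))
  rows <- list()
  nextlab <- 0L
  for (sgn in c(1, -1)) {
    supra <- (sgn * tvol) > tc & contrast$mask
    if (!any(supra)) next
    lab <- label_clusters(supra, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    for (l in which(sizes >= k_crit)) {
      nextlab <- nextlab + 1L
      vox <- which(lab == l)
      labels[vox] <- nextlab
      pk <- vox[which.max(sgn * tvol[vox])]
      pk_mm <- vox_to_mm(contrast$grid, arrayInd(pk, dim(tvol)))
      rows[[nextlab]] <- data.frame(
        label = nextlab, size = sizes[l],
        peak_x_mm = pk_mm[1], peak_y_mm = pk_mm[2], peak_z_mm = pk_mm[3],
        peak_t = tvol[pk], sign = sgn
      )
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(), size = integer(), peak_x_mm = numeric(),
               peak_y_mm = numeric(), peak_z_mm = numeric(),
               peak_t = numeric(), sign = numeric())
  structure(list(t = tvol, df = contrast$df, labels = labels,
                 clusters = clusters, grid = contrast$grid,
                 mask = contrast$mask, p_voxel = p_voxel, k_crit = k_crit,
                 connectivity = connectivity),
            class = "cluster_result")
}

#' Conjunction of two thresholded results
#'
#' A voxel is kept iff it belongs to a surviving cluster in both results
#' with the same sign of effect; the intersection is re-labelled into
#' connected components with size, peak (of the mean of the two t maps) and
#' sign — the regions showing common change in both patient-versus-control
#' comparisons.
#'
#' @param result_a,result_b `cluster_result` objects on the same grid,
#'   thresholded identically.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return object of class `cluster_result` (with `t` the mean t map).
#' @export
conjunction <- function(result_a, result_b, connectivity = 26L) {
  stop_if_grid_mismatch(result_a$grid, result_b$grid, "conjunction inputs")
  sign_a <- sign(result_a$t) * (result_a$labels > 0L)
  sign_b <- sign(result_b$t) * (result_b$labels > 0L)
  keep <- sign_a != 0 & sign_a == sign_b
  tmean <- (result_a$t + result_b$t) / 2
  labels <- array(0L, dim = dim(keep))
  rows <- list()
  nextlab <- 0L
  for (sgn in c(1, -1)) {
    m <- keep & sign_a == sgn
    if (!any(m)) next
    lab <- label_clusters(m, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    for (l in seq_along(sizes)) {
      nextlab <- nextlab + 1L
      vox <- which(lab == l)
      labels[vox] <- nextlab
      pk <- vox[which.max(sgn * tmean[vox])]
      pk_mm <- vox_to_mm(result_a$grid, arrayInd(pk, dim(keep)))
      rows[[nextlab]] <- data.frame(
        label = nextlab, size = sizes[l],
        peak_x_mm = pk_mm[1], peak_y_mm = pk_mm[2], peak_z_mm = pk_mm[3],
        peak_t = tmean[pk], sign = sgn
      )
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(), size = integer(), peak_x_mm = numeric(),
               peak_y_mm = numeric(), peak_z_mm = numeric(),
               peak_t = numeric(), sign = numeric())
  structure(list(t = tmean, df = min(result_a$df, result_b$df),
                 labels = labels, clusters = clusters, grid = result_a$grid,
                 mask = result_a$mask & result_b$mask,
                 p_voxel = result_a$p_voxel, k_crit = result_a$k_crit,
                 connectivity = connectivity),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), p_voxel %g, k_crit %d\n",
              nrow(x$clusters), x$p_voxel, x$k_crit))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}
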