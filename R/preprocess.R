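#' BOLD time-series container
#'
#' A 4D BOLD series (x, y, z, t) on a template grid, with its repetition
#' time and brain mask. Values inside the mask must be finite.
#'
#' @param data 4D numeric array.
#' @param grid a `template_grid`.
#' @param tr_s repetition time in seconds.
#' @param mask logical 3D array (brain mask).
#' @return object of class `bold_series`.
#' @export
bold_series <- function(data, grid, tr_s, mask) {
  stopifnot(length(dim(data)) == 4L, tr_s > 0)
  if (!all(dim(data)[1:3] == grid$shape)) {
    stop("data spatial shape does not match grid", call. = FALSE)
  }
  if (!all(dim(mask) == grid$shape)) {
    stop("mask shape does not match grid", call. = FALSE)
  }
  nt <- dim(data)[4]
  if (nt < 2L) stop("need at least 2 timepoints", call. = FALSE)
  structure(list(data = data, grid = grid, tr_s = tr_s, mask = mask),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %s voxels x %d timepoints, TR %g s, %d in mask\n",
              paste(dim(x$data)[1:3], collapse = " x "), dim(x$data)[4],
              x$tr_s, sum(x$mask)))
  invisible(x)
}

n_timepoints <- function(series) dim(series$data)[4]

# voxels x time matrix view of a series (time is the last array dim, so
# flattening gives it directly)
as_voxel_matrix <- function(series) {
  matrix(series$data, nrow = prod(series$grid$shape), ncol = n_timepoints(series))
}

from_voxel_matrix <- function(m, series) {
  bold_series(array(m, dim = c(series$grid$shape, ncol(m))),
              series$grid, series$tr_s, series$mask)
}

#' Discard initial volumes
#'
#' Drops the first `n_discard` volumes (magnetisation-stabilisation scans);
#' with the default 3, a 165-volume acquisition keeps 162.
#'
#' @param series a `bold_series`.
#' @param n_discard number of leading volumes to drop (default 3).
#' @return the shortened `bold_series`.
#' @export
discard_initial <- function(series, n_discard = 3L) {
  nt <- n_timepoints(series)
  if (n_discard >= nt) {
    stop(sprintf("cannot discard %d of %d volumes", n_discard, nt), call. = FALSE)
  }
  if (n_discard == 0L) return(series)
  bold_series(series$data[, , , (n_discard + 1):nt, drop = FALSE],
              series$grid, series$tr_s, series$mask)
}

#' Motion quality control
#'
#' A subject fails QC iff the maximal displacement — per-axis absolute
#' deviation from the first volume — exceeds `max_mm` on any translation
#' axis or `max_deg` on any rotation axis, strictly ("more than"): exactly
#' 3.0 mm passes under the defaults.
#'
#' @param trace numeric matrix, timepoints x 6 (3 translations mm, 3
#'   rotations degrees).
#' @param max_mm translation limit (default 3).
#' @param max_deg rotation limit (default 3).
#' @return list with `pass` (logical), `max_translation_mm`,
#'   `max_rotation_deg`, and `offending` (data.frame of violating samples).
#' @export
motion_qc <- function(trace, max_mm = 3, max_deg = 3) {
  trace <- as.matrix(trace)
  if (nrow(trace) == 0L) stop("empty motion trace", call. = FALSE)
  stopifnot(ncol(trace) == 6L, all(is.finite(trace)))
  disp <- abs(sweep(trace, 2L, trace[1L, ]))
  viol <- which((disp > cbind(matrix(max_mm, nrow(disp), 3),
                              matrix(max_deg, nrow(disp), 3))),
                arr.ind = TRUE)
  offending <- data.frame(
    timepoint = viol[, 1],
    axis = colnames(trace)[viol[, 2]] %||% viol[, 2],
    displacement = disp[viol],
    stringsAsFactors = FALSE
  )
  list(pass = nrow(offending) == 0L,
       max_translation_mm = max(disp[, 1:3]),
       max_rotation_deg = max(disp[, 4:6]),
       offending = offending)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove per-voxel linear trends
#'
#' Least-squares line (intercept + slope) removed from every voxel's series;
#' the removed per-voxel mean is kept as attribute `voxel_mean` for any
#' amplitude reporting. Idempotent.
#'
#' @param series a `bold_series`.
#' @return detrended `bold_series` (per-voxel mean ~ 0).
#' @export
detrend_linear <- function(series) {
  nt <- n_timepoints(series)
  if (nt < 3L) stop("need at least 3 timepoints to detrend", call. = FALSE)
  M <- as_voxel_matrix(series)
  tc <- seq_len(nt) - (nt + 1) / 2
  mu <- rowMeans(M)
  beta <- (M %*% tc) / sum(tc^2)
  R <- M - mu - tcrossprod(beta, tc)
  out <- from_voxel_matrix(R, series)
  attr(out, "voxel_mean") <- array(mu, dim = series$grid$shape)
  out
}

# Folded bin frequencies of a length-n DFT sampled at interval tr_s.
bin_freqs <- function(n, tr_s) {
  k <- seq_len(n) - 1L
  pmin(k, n - k) / (n * tr_s)
}

# Ideal rectangular spectral filter applied to the columns of a t x k
# matrix. Bin kept iff f_lo <= f_bin <= f_hi; DC always removed.
filter_columns <- function(m, tr_s, f_lo, f_hi) {
  n <- nrow(m)
  f <- bin_freqs(n, tr_s)
  keep <- f >= f_lo & f <= f_hi
  keep[1L] <- FALSE
  X <- stats::mvfft(m)
  X[!keep, ] <- 0
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

#' Ideal band-pass filter
#'
#' Frequency-domain rectangular filter: DFT coefficients whose bin frequency
#' lies outside `[f_lo, f_hi]` are zeroed (band-inclusive at both edges; DC
#' always removed) and the series inverse-transformed. Exact on-bin
#' pass-through and rejection make band edges testable to machine precision.
#'
#' @param series a `bold_series`.
#' @param f_lo,f_hi band edges in Hz (defaults 0.01 and 0.08).
#' @return filtered `bold_series`.
#' @export
bandpass_ideal <- function(series, f_lo = 0.01, f_hi = 0.08) {
  nyq <- 1 / (2 * series$tr_s)
  if (f_hi > nyq + 1e-12) {
    stop(sprintf("f_hi = %g Hz exceeds Nyquist %g Hz", f_hi, nyq), call. = FALSE)
  }
  stopifnot(f_lo >= 0, f_lo < f_hi)
  M <- as_voxel_matrix(series)
  from_voxel_matrix(t(filter_columns(t(M), series$tr_s, f_lo, f_hi)), series)
}

#' Nuisance regressor set
#'
#' Nine columns: the six motion parameters plus the mean CSF, WM and global
#' (whole-brain) signals, each of length t.
#'
#' @param motion timepoints x 6 matrix.
#' @param csf_mean,wm_mean,global_mean numeric vectors of length t.
#' @return timepoints x 9 matrix of class `nuisance_set`.
#' @export
nuisance_set <- function(motion, csf_mean, wm_mean, global_mean) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6L,
            length(csf_mean) == nrow(motion),
            length(wm_mean) == nrow(motion),
            length(global_mean) == nrow(motion))
  m <- cbind(motion, csf = csf_mean, wm = wm_mean, global = global_mean)
  if (!all(is.finite(m))) stop("nuisance columns must be finite", call. = FALSE)
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
                   "csf", "wm", "global")
  structure(m, class = c("nuisance_set", "matrix"))
}

#' Build the nuisance set from a series and tissue masks
#'
#' CSF/WM means are computed over the corresponding label masks and the
#' global mean over the brain mask.
#'
#' @param series a `bold_series`.
#' @param motion timepoints x 6 motion matrix.
#' @param masks named list with logical arrays `csf`, `wm`, `brain`.
#' @return a [nuisance_set()].
#' @export
compute_nuisance <- function(series, motion, masks) {
  M <- as_voxel_matrix(series)
  nuisance_set(motion,
               colMeans(M[which(masks$csf), , drop = FALSE]),
               colMeans(M[which(masks$wm), , drop = FALSE]),
               colMeans(M[which(masks$brain), , drop = FALSE]))
}

#' Regress out nuisance signals
#'
#' Per-voxel OLS on the 9 nuisance regressors plus an intercept; returns the
#' residuals, which are orthogonal to every regressor. A rank-deficient
#' design is an error naming the collinear columns.
#'
#' @param series a `bold_series`.
#' @param nuisance a [nuisance_set()] (timepoints x 9).
#' @return residual `bold_series`.
#' @export
regress_nuisance <- function(series, nuisance) {
  nt <- n_timepoints(series)
  nuisance <- unclass(nuisance)
  if (nrow(nuisance) != nt) {
    stop("nuisance length does not match series", call. = FALSE)
  }
  X <- cbind(intercept = 1, nuisance)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  R <- t(qr.resid(qx, t(as_voxel_matrix(series))))
  from_voxel_matrix(R, series)
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  C <- matrix(0, n, n)
  for (d in -r:r) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    C[cbind(i[ok], j[ok])] <- kernel[d + r + 1L]
  }
  C
}

apply_along_axis <- function(arr, C, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  m <- C %*% matrix(a, nrow = d[axis])
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

#' Isotropic Gaussian smoothing
#'
#' Separable spatial convolution with a Gaussian of the given FWHM in mm,
#' converted per axis to voxel units via `sigma = FWHM / (2 sqrt(2 ln 2)) /
#' voxel_size` and truncated at 4 sigma with the kernel normalised to unit
#' mass. `fwhm_mm = 0` is the identity. With `mask` supplied, the result is
#' renormalised by the smoothed mask so in-mask values are not diluted at
#' edges.
#'
#' @param x 3D array, 4D array, or `bold_series`.
#' @param fwhm_mm kernel full width at half maximum, mm (>= 0).
#' @param grid the `template_grid` (taken from the series if omitted).
#' @param mask optional logical array for mask-aware renormalisation.
#' @return object of the same type as `x`.
#' @export
smooth_gaussian <- function(x, fwhm_mm, grid = NULL, mask = NULL) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative", call. = FALSE)
  if (inherits(x, "bold_series")) {
    out <- x
    out$data <- smooth_gaussian(x$data, fwhm_mm, x$grid, mask)
    return(out)
  }
  if (is.null(grid)) stop("grid required for array input", call. = FALSE)
  if (fwhm_mm == 0) return(x)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / grid$voxel_size_mm
  Cs <- lapply(1:3, function(a) conv_matrix(grid$shape[a], gaussian_kernel_1d(sigma[a])))
  run <- function(arr) {
    for (a in 1:3) arr <- apply_along_axis(arr, Cs[[a]], a)
    arr
  }
  smooth_one <- run
  if (is.null(mask)) return(run(x))
  sm_mask <- smooth_one(array(as.numeric(mask), dim = grid$shape))
  res <- run(x * as.numeric(mask))
  scale <- ifelse(sm_mask > 1e-12, 1 / sm_mask, 0)
  if (length(dim(x)) == 3L) res * scale else res * as.numeric(scale)
}

#' Branch preprocessing pipelines
#'
#' The two analysis branches apply the temporal cleaning in the order the
#' metric definitions require: the ReHo branch is detrend, band-pass,
#' nuisance regression (regressors band-passed identically to the data; no
#' smoothing — ReHo images are never smoothed); the ALFF/fALFF branch is
#' detrend, nuisance regression, 4-mm smoothing, with no temporal filtering
#' because the frequency band is applied spectrally inside the ALFF/fALFF
#' computation (pre-filtering would drive fALFF to 1). `order = "literal"`
#' instead applies smoothing (ALFF branch only), band-pass, detrend,
#' regression in that sequence, the order the processing description lists.
#'
#' @param series raw `bold_series` (after [discard_initial()]).
#' @param motion timepoints x 6 motion matrix (matching the retained
#'   volumes).
#' @param masks named list with `csf`, `wm`, `brain` logical arrays.
#' @param branch `"reho"` or `"alff"`.
#' @param f_lo,f_hi band edges in Hz.
#' @param fwhm_mm smoothing kernel for the ALFF branch (default 4).
#' @param order `"metric"` (default) or `"literal"`.
#' @return preprocessed `bold_series`.
#' @export
preprocess_branch <- function(series, motion, masks, branch = c("reho", "alff"),
                              f_lo = 0.01, f_hi = 0.08, fwhm_mm = 4,
                              order = c("metric", "literal")) {
  branch <- match.arg(branch)
  order <- match.arg(order)
  if (nrow(motion) != n_timepoints(series)) {
    motion <- motion[seq_len(n_timepoints(series)) +
                       (nrow(motion) - n_timepoints(series)), , drop = FALSE]
  }
  if (order == "literal") {
    s <- series
    if (branch == "alff") s <- smooth_gaussian(s, fwhm_mm)
    s <- bandpass_ideal(s, f_lo, f_hi)
    s <- detrend_linear(s)
    ns <- compute_nuisance(s, filter_columns(motion, series$tr_s, f_lo, f_hi), masks)
    return(regress_nuisance(s, ns))
  }
  s <- detrend_linear(series)
  if (branch == "reho") {
    s <- bandpass_ideal(s, f_lo, f_hi)
    ns <- compute_nuisance(s, filter_columns(motion, series$tr_s, f_lo, f_hi), masks)
    regress_nuisance(s, ns)
  } else {
    ns <- compute_nuisance(s, sweep(motion, 2L, colMeans(motion)), masks)
    s <- regress_nuisance(s, ns)
    smooth_gaussian(s, fwhm_mm)
  }
}
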