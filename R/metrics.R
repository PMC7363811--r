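#' Metric map container
#'
#' A 3D voxel map of one resting-state metric with its normalisation state.
#' Raw ReHo and fALFF values lie in `[0, 1]`; a `global_mean_divided` map
#' has mean 1 over the mask.
#'
#' @param data 3D numeric array.
#' @param metric `"reho"`, `"alff"` or `"falff"`.
#' @param normalization `"raw"`, `"global_mean_divided"` or `"zscore"`.
#' @param mask logical 3D array.
#' @param band numeric(2) band edges for alff/falff, else NULL.
#' @param qc list of QC counts (degenerate voxels etc.).
#' @return object of class `metric_map`.
#' @export
metric_map <- function(data, metric, normalization, mask, band = NULL, qc = list()) {
  metric <- match.arg(metric, c("reho", "alff", "falff"))
  normalization <- match.arg(normalization, c("raw", "global_mean_divided", "zscore"))
  stopifnot(all(dim(data) == dim(mask)))
  if (!all(is.finite(data[mask]))) {
    stop("metric map contains non-finite values inside the mask", call. = FALSE)
  }
  structure(list(data = data, metric = metric, normalization = normalization,
                 mask = mask, band = band, qc = qc),
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  cat(sprintf("<metric_map> %s (%s), %d in-mask voxels, mean %.4g\n",
              x$metric, x$normalization, sum(x$mask), mean(x$data[x$mask])))
  invisible(x)
}

#' Kendall's coefficient of concordance for one neighbourhood
#'
#' For K series of n timepoints, each series is ranked (ascending, average
#' ranks for ties), `R_i` is the sum of ranks at timepoint i, and
#' `W = (sum R_i^2 - n Rbar^2) / (K^2 (n^3 - n) / 12)`, which lies in
#' `[0, 1]`: 1 means perfectly synchronised series. Tiny negative floating
#' error (> -1e-12) is clamped to 0. A zero-variance series makes the
#' neighbourhood degenerate: the configured degenerate value is returned
#' with attribute `degenerate = TRUE`.
#'
#' @param x numeric matrix, n timepoints x K series (n >= 2, K >= 2).
#' @param degenerate_value value returned for degenerate neighbourhoods.
#' @return numeric scalar.
#' @export
kcc <- function(x, degenerate_value = 0) {
  x <- as.matrix(x)
  n <- nrow(x); K <- ncol(x)
  if (n < 2L || K < 2L) stop("kcc needs n >= 2 and K >= 2", call. = FALSE)
  v <- apply(x, 2L, function(col) max(col) - min(col))
  if (any(v == 0)) {
    return(structure(degenerate_value, degenerate = TRUE))
  }
  ranks <- apply(x, 2L, rank)
  R_i <- rowSums(ranks)
  W <- (sum(R_i^2) - n * mean(R_i)^2) / (K^2 * (n^3 - n) / 12)
  if (W < 0 && W > -1e-12) W <- 0
  W
}

neighborhood_offsets <- function(neighborhood) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  w <- rowSums(abs(off))
  switch(as.character(neighborhood),
         "7" = off[w <= 1L, , drop = FALSE],
         "19" = off[w <= 2L, , drop = FALSE],
         "27" = off,
         stop("neighborhood must be 7, 19 or 27", call. = FALSE))
}

#' Voxel-wise regional homogeneity map
#'
#' KCC of every in-mask voxel's time series with its neighbours (default:
#' the 26 nearest, i.e. a 27-voxel cube). At mask edges only the in-mask
#' subset of the neighbourhood is used (K = its size); voxels with fewer
#' than `k_min` in-mask members, or whose neighbourhood contains a
#' zero-variance series, receive `degenerate_value` and are counted in the
#' QC record. Input should be ReHo-branch preprocessed (band-passed
#' residuals, unsmoothed).
#'
#' @param series a preprocessed `bold_series`.
#' @param neighborhood 7, 19 or 27 (default 27).
#' @param k_min minimum in-mask neighbourhood size (default 14).
#' @param degenerate_value value written for degenerate voxels (default 0).
#' @return a raw `metric_map` (`metric = "reho"`).
#' @export
reho_map <- function(series, neighborhood = 27L, k_min = 14L, degenerate_value = 0) {
  mask <- series$mask
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  sh <- series$grid$shape
  nt <- n_timepoints(series)
  M <- as_voxel_matrix(series)
  inmask <- which(mask)
  rng <- apply(M[inmask, , drop = FALSE], 1L, function(r) max(r) - min(r))
  zerovar <- logical(prod(sh))
  zerovar[inmask[rng == 0]] <- TRUE
  # per-voxel ranks (average ranks for ties); zero rows outside the mask
  Rk <- matrix(0, nrow = prod(sh), ncol = nt)
  Rk[inmask, ] <- t(apply(M[inmask, , drop = FALSE], 1L, rank))

  ijk <- arrayInd(seq_len(prod(sh)), sh)
  off <- neighborhood_offsets(neighborhood)
  S <- matrix(0, nrow = prod(sh), ncol = nt)
  Kmap <- integer(prod(sh))
  zvcount <- integer(prod(sh))
  for (o in seq_len(nrow(off))) {
    ni <- ijk[, 1] + off[o, 1]; nj <- ijk[, 2] + off[o, 2]; nk <- ijk[, 3] + off[o, 3]
    ok <- ni >= 1L & ni <= sh[1] & nj >= 1L & nj <= sh[2] & nk >= 1L & nk <= sh[3]
    lin <- ni[ok] + (nj[ok] - 1L) * sh[1] + (nk[ok] - 1L) * sh[1] * sh[2]
    use <- mask[lin]
    rows <- which(ok)[use]
    lin <- lin[use]
    S[rows, ] <- S[rows, ] + Rk[lin, , drop = FALSE]
    Kmap[rows] <- Kmap[rows] + 1L
    zvcount[rows] <- zvcount[rows] + zerovar[lin]
  }
  n <- nt
  Rbar <- rowSums(S) / n
  num <- rowSums(S^2) - n * Rbar^2
  den <- Kmap^2 * (n^3 - n) / 12
  W <- ifelse(den > 0, num / den, 0)
  W[W < 0 & W > -1e-12] <- 0
  degen <- (Kmap < k_min) | (zvcount > 0)
  W[degen] <- degenerate_value
  W[!mask] <- 0
  metric_map(array(W, dim = sh), "reho", "raw", mask,
             qc = list(degenerate_voxels = sum(degen & mask),
                       k_min = k_min, neighborhood = nrow(off)))
}

# Single-sided amplitude spectrum of the columns of a t x V matrix:
# amplitude_k = 2 |X_k| / n for 0 < k < Nyquist, |X_k| / n at the Nyquist
# bin (even n). Row b corresponds to frequency b / (n tr_s), DC dropped.
amplitude_spectrum <- function(M_t_by_v, tr_s) {
  n <- nrow(M_t_by_v)
  X <- stats::mvfft(M_t_by_v)
  kmax <- floor(n / 2)
  A <- 2 * Mod(X[2:(kmax + 1), , drop = FALSE]) / n
  if (n %% 2 == 0) A[kmax, ] <- A[kmax, ] / 2
  freqs <- (1:kmax) / (n * tr_s)
  list(A = A, freqs = freqs)
}

# amplitude spectrum restricted to in-mask voxels of a series
mask_spectrum <- function(series) {
  M <- as_voxel_matrix(series)
  idx <- which(series$mask)
  sp <- amplitude_spectrum(t(M[idx, , drop = FALSE]), series$tr_s)
  sp$idx <- idx
  sp
}

fill_map <- function(vals_inmask, idx, shape) {
  out <- numeric(prod(shape))
  out[idx] <- vals_inmask
  array(out, dim = shape)
}

band_rows <- function(freqs, f_lo, f_hi, n, tr_s) {
  rows <- which(freqs >= f_lo & freqs <= f_hi)
  if (length(rows) == 0L) {
    min_t <- ceiling(1 / (f_hi * tr_s))
    stop(sprintf("no frequency bins in [%g, %g] Hz; need t >= %d at TR %g s",
                 f_lo, f_hi, min_t, tr_s), call. = FALSE)
  }
  rows
}

#' Amplitude of low-frequency fluctuation map
#'
#' Per voxel, the series is Fourier transformed, the square root of the
#' power taken at each frequency (the single-sided amplitude spectrum,
#' `2 |X_k| / n` for interior bins), and ALFF is the mean amplitude over the
#' bins with `f_lo <= f <= f_hi` (DC excluded). Input should be ALFF-branch
#' preprocessed (detrended, regressed, smoothed, unfiltered).
#'
#' @param series a preprocessed `bold_series`.
#' @param f_lo,f_hi band edges in Hz (defaults 0.01 and 0.08).
#' @return a raw `metric_map` (`metric = "alff"`).
#' @export
alff_map <- function(series, f_lo = 0.01, f_hi = 0.08) {
  sp <- mask_spectrum(series)
  rows <- band_rows(sp$freqs, f_lo, f_hi, n_timepoints(series), series$tr_s)
  vals <- colMeans(sp$A[rows, , drop = FALSE])
  metric_map(fill_map(vals, sp$idx, series$grid$shape), "alff", "raw",
             series$mask, band = c(f_lo, f_hi))
}

#' Fractional ALFF map
#'
#' Ratio of the amplitude sum over the in-band bins to the amplitude sum
#' over the entire detectable range (first positive-frequency bin through
#' Nyquist, DC excluded); lies in `[0, 1]`. All-zero series (0/0) receive
#' `degenerate_value` and a QC count.
#'
#' @inheritParams alff_map
#' @param degenerate_value value for 0/0 voxels (default 0).
#' @return a raw `metric_map` (`metric = "falff"`).
#' @export
falff_map <- function(series, f_lo = 0.01, f_hi = 0.08, degenerate_value = 0) {
  sp <- mask_spectrum(series)
  rows <- band_rows(sp$freqs, f_lo, f_hi, n_timepoints(series), series$tr_s)
  num <- colSums(sp$A[rows, , drop = FALSE])
  den <- colSums(sp$A)
  vals <- ifelse(den > 0, num / den, degenerate_value)
  metric_map(fill_map(vals, sp$idx, series$grid$shape), "falff", "raw",
             series$mask, band = c(f_lo, f_hi),
             qc = list(degenerate_voxels = sum(den == 0)))
}

#' Normalise a metric map
#'
#' `global_mean_divided`: each in-mask voxel divided by the in-mask mean
#' (the map then has mask mean 1). `zscore`: in-mask mean subtracted and
#' divided by the in-mask sd. Out-of-mask voxels are set to 0.
#'
#' @param map a raw `metric_map`.
#' @param mode `"global_mean_divided"` or `"zscore"`.
#' @return the normalised `metric_map`.
#' @export
normalize_map <- function(map, mode = c("global_mean_divided", "zscore")) {
  mode <- match.arg(mode)
  if (map$normalization != "raw") {
    stop("normalize_map expects a raw map", call. = FALSE)
  }
  v <- map$data[map$mask]
  out <- array(0, dim = dim(map$data))
  if (mode == "global_mean_divided") {
    mu <- mean(v)
    if (abs(mu) < 1e-300) stop("mask mean is zero; cannot divide", call. = FALSE)
    out[map$mask] <- v / mu
  } else {
    mu <- mean(v); s <- stats::sd(v)
    if (s == 0) stop("mask sd is zero; cannot z-score", call. = FALSE)
    out[map$mask] <- (v - mu) / s
  }
  metric_map(out, map$metric, mode, map$mask, band = map$band, qc = map$qc)
}
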