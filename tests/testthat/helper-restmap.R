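# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written from first principles (loops, direct summation) and
# never call the implementation they check.

small_grid <- function() template_grid(c(10L, 12L, 10L), 3)

# a minimal template on a reduced grid for fast end-to-end tests
small_layout <- function() {
  list(
    csf = list(label = 3L, center_mm = c(0, 0, 6), half_mm = c(2, 3, 1)),
    wm = list(label = 2L, center_mm = c(0, 0, 12), half_mm = c(5, 6, 2)),
    caudate_l = list(label = 10L, center_mm = c(-6, 3, 0), half_mm = c(2, 4, 4)),
    caudate_r = list(label = 11L, center_mm = c(6, 3, 0), half_mm = c(2, 4, 4)),
    putamen_l = list(label = 12L, center_mm = c(-12, -1.5, -3), half_mm = c(2, 7.5, 7.5)),
    putamen_r = list(label = 13L, center_mm = c(12, -1.5, -3), half_mm = c(2, 7.5, 7.5)),
    occipital_ref = list(label = 20L, center_mm = c(0, -13, 0), half_mm = c(5, 3, 4)),
    insula = list(label = 30L, center_mm = c(12, 6, 6), half_mm = c(2, 2, 2))
  )
}

small_template <- function() make_template(small_grid(), small_layout())

# one large central region with a proper 3x3x3 interior, for synchrony tests
sync_template <- function() {
  make_template(small_grid(), list(
    insula = list(label = 30L, center_mm = c(0, 0, 0), half_mm = c(6, 6, 6))
  ))
}

# voxels of `mask` whose full 27-neighbourhood stays inside `mask`
region_interior <- function(mask) {
  sh <- dim(mask)
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    sx <- pmin(pmax(seq_len(sh[1]) + dx, 1L), sh[1])
    sy <- pmin(pmax(seq_len(sh[2]) + dy, 1L), sh[2])
    sz <- pmin(pmax(seq_len(sh[3]) + dz, 1L), sh[3])
    shifted <- mask[sx, sy, sz]
    # voxels at the array border with a neighbour outside the grid fail too
    border <- outer(outer(seq_len(sh[1]) + dx < 1 | seq_len(sh[1]) + dx > sh[1],
                          seq_len(sh[2]) + dy < 1 | seq_len(sh[2]) + dy > sh[2], `|`),
                    seq_len(sh[3]) + dz < 1 | seq_len(sh[3]) + dz > sh[3], `|`)
    out <- out & shifted & !border
  }
  out
}

# constant-signal-free BOLD fixture: deterministic sinusoid + optional noise
make_series <- function(signal, grid = small_grid(), tr_s = 2,
                        mask = array(TRUE, dim = grid$shape)) {
  nt <- length(signal)
  data <- array(rep(signal, each = prod(grid$shape)), dim = c(grid$shape, nt))
  bold_series(data, grid, tr_s, mask)
}

# Kendall's W from first principles: explicit rank computation via sorting,
# then 12 * sum((R_i - Rbar)^2) / (K^2 (n^3 - n)).
oracle_kendall_w <- function(x) {
  n <- nrow(x); K <- ncol(x)
  ranks <- matrix(0, n, K)
  for (j in seq_len(K)) {
    ord <- order(x[, j])
    r <- numeric(n)
    i <- 1L
    while (i <= n) {
      ties <- which(x[, j] == x[ord[i], j])
      r[ties] <- mean(match(ties, ord))
      i <- i + length(ties)
    }
    ranks[, j] <- r
  }
  R_i <- rowSums(ranks)
  12 * sum((R_i - mean(R_i))^2) / (K^2 * (n^3 - n))
}

# direct-summation DFT amplitude at one frequency index k (1 = first
# positive bin), matching the declared single-sided convention
oracle_dft_amplitude <- function(x, k) {
  n <- length(x)
  tt <- 0:(n - 1)
  re <- sum(x * cos(-2 * pi * k * tt / n))
  im <- sum(x * sin(-2 * pi * k * tt / n))
  a <- 2 * sqrt(re^2 + im^2) / n
  if (n %% 2 == 0 && k == n / 2) a / 2 else a
}

# exhaustive stack-based flood fill, independent of the igraph labelling
oracle_max_cluster <- function(vol, connectivity = 26L) {
  sh <- dim(vol)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6L) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  if (connectivity == 18L) off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  seen <- array(FALSE, dim = sh)
  best <- 0L
  for (v in which(vol)) {
    if (seen[v]) next
    stack <- v; seen[v] <- TRUE; size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      size <- size + 1L
      ijk <- arrayInd(cur, sh)
      for (o in seq_len(nrow(off))) {
        p <- ijk + off[o, ]
        if (any(p < 1L) || any(p > sh)) next
        lin <- p[1] + (p[2] - 1L) * sh[1] + (p[3] - 1L) * sh[1] * sh[2]
        if (vol[lin] && !seen[lin]) { seen[lin] <- TRUE; stack <- c(stack, lin) }
      }
    }
    best <- max(best, size)
  }
  best
}

# independent normal-equations OLS: beta = (X'X)^-1 X'y, residuals, t stat
oracle_ols <- function(X, y) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  list(beta = drop(beta), resid = drop(res),
       t = drop(beta) / sqrt(diag(XtXi) * s2), df = df)
}

fisher_ci <- function(rho, n, level = 0.95) {
  z <- atanh(rho)
  hw <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - hw, z + hw))
}
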