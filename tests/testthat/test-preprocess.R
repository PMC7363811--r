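test_that("initial-volume discarding keeps the expected count and validates", {
  g <- small_grid()
  s <- make_series(rnorm(165), g)
  expect_identical(dim(discard_initial(s)$data)[4], 162L)
  expect_identical(discard_initial(s, 0), s)
  expect_error(discard_initial(s, 165), "discard")
  # the retained volumes are the trailing ones
  expect_equal(discard_initial(s, 3)$data[1, 1, 1, 1], s$data[1, 1, 1, 4])
})

test_that("motion QC applies the strict more-than rule per axis", {
  tr <- matrix(0, 100, 6,
               dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                       "rot_x", "rot_y", "rot_z")))
  expect_true(motion_qc(tr)$pass)
  tr2 <- tr; tr2[50, 2] <- 3.1
  qc <- motion_qc(tr2)
  expect_false(qc$pass)
  expect_identical(qc$offending$timepoint, 50L)
  expect_identical(qc$offending$axis, "trans_y")
  tr3 <- tr; tr3[50, 2] <- 3.0; tr3[70, 5] <- 3.0
  expect_true(motion_qc(tr3)$pass)      # exactly 3.0 is not "more than"
  tr4 <- tr; tr4[12, 5] <- -3.2         # rotations checked on magnitude
  expect_false(motion_qc(tr4)$pass)
  # displacement is measured relative to the first volume
  tr5 <- tr + 10
  expect_true(motion_qc(tr5)$pass)
  expect_error(motion_qc(tr[0, ]), "empty")
})

test_that("linear detrending removes exactly the fitted line", {
  g <- template_grid(c(2, 2, 2), 3)
  nt <- 60
  tt <- seq_len(nt)
  line <- 5 + 0.3 * tt
  s <- make_series(line, g)
  out <- detrend_linear(s)
  expect_lt(max(abs(out$data)), 1e-10)
  # line + sinusoid: the sinusoid's own OLS line fit must be removed with it
  sine <- sin(2 * pi * 7 * (tt - 1) / nt)
  X <- cbind(1, tt)
  resid_oracle <- sine - X %*% solve(crossprod(X), crossprod(X, sine))
  s2 <- make_series(line + 2 * sine, g)
  out2 <- detrend_linear(s2)
  expect_lt(max(abs(out2$data[1, 1, 1, ] - 2 * resid_oracle)), 1e-8 * 2)
  # idempotence and stored mean
  expect_equal(detrend_linear(out2)$data, out2$data, tolerance = 1e-12)
  expect_equal(attr(out2, "voxel_mean")[1, 1, 1], mean(line + 2 * sine))
})

test_that("ideal band-pass passes on-bin in-band tones and rejects out-of-band", {
  g <- template_grid(c(2, 2, 1), 3)
  nt <- 200; tr_s <- 2                      # bins at k/400 Hz
  tt <- 0:(nt - 1)
  inband <- sin(2 * pi * 16 * tt / nt)      # 0.04 Hz
  outband <- sin(2 * pi * 80 * tt / nt)     # 0.20 Hz, on-bin
  s_in <- bandpass_ideal(make_series(inband, g, tr_s = tr_s))
  expect_lt(max(abs(s_in$data[1, 1, 1, ] - inband)), 1e-10)
  s_out <- bandpass_ideal(make_series(outband, g, tr_s = tr_s))
  expect_lt(sqrt(mean(s_out$data[1, 1, 1, ]^2)),
            1e-10 * sqrt(mean(outband^2)))
  # band-inclusive edges: 0.01 and 0.08 Hz exactly on-bin are kept
  for (k in c(4, 32)) {                     # k/400 = 0.01, 0.08
    tone <- cos(2 * pi * k * tt / nt)
    out <- bandpass_ideal(make_series(tone, g, tr_s = tr_s))
    expect_lt(max(abs(out$data[1, 1, 1, ] - tone)), 1e-10)
  }
  expect_error(bandpass_ideal(make_series(inband, g, tr_s = 2), 0.01, 0.3),
               "Nyquist")
})

test_that("band-pass output variance obeys the Parseval identity", {
  g <- template_grid(c(1, 1, 1), 3)
  set.seed(31)
  nt <- 128; tr_s <- 2
  x <- rnorm(nt)
  out <- bandpass_ideal(make_series(x, g, tr_s = tr_s), 0.01, 0.08)$data[1, 1, 1, ]
  # oracle: direct DFT, sum |X_k|^2 over retained bins / n^2
  k <- 0:(nt - 1)
  f <- pmin(k, nt - k) / (nt * tr_s)
  keep <- f >= 0.01 & f <= 0.08 & k > 0
  Xk <- vapply(k, function(kk) sum(x * exp(-2i * pi * kk * (0:(nt - 1)) / nt)),
               complex(1))
  expect_equal(sum(out^2), sum(Mod(Xk[keep])^2) / nt, tolerance = 1e-10)
})

test_that("nuisance regression residuals match the normal-equations oracle", {
  g <- template_grid(c(5, 1, 1), 3)
  set.seed(7)
  nt <- 80
  motion <- matrix(rnorm(nt * 6), nt)
  ns <- nuisance_set(motion, rnorm(nt), rnorm(nt), rnorm(nt))
  Y <- matrix(rnorm(5 * nt), nrow = 5)
  s <- bold_series(array(Y, dim = c(5, 1, 1, nt)), g, 2,
                   array(TRUE, dim = c(5, 1, 1)))
  out <- regress_nuisance(s, ns)
  X <- cbind(1, unclass(ns))
  for (v in 1:5) {
    expect_equal(out$data[v, 1, 1, ], oracle_ols(X, Y[v, ])$resid,
                 tolerance = 1e-10)
  }
  # residuals orthogonal to every regressor
  R <- matrix(out$data, nrow = 5)
  dots <- abs(R %*% unclass(ns)) / (sqrt(rowSums(R^2)) %o% sqrt(colSums(unclass(ns)^2)))
  expect_lt(max(dots), 1e-8)
  # idempotence
  expect_equal(regress_nuisance(out, ns)$data, out$data, tolerance = 1e-8)
  # a voxel equal to a motion column regresses to zero
  Y2 <- Y; Y2[3, ] <- motion[, 4]
  s2 <- bold_series(array(Y2, dim = c(5, 1, 1, nt)), g, 2,
                    array(TRUE, dim = c(5, 1, 1)))
  expect_lt(max(abs(regress_nuisance(s2, ns)$data[3, 1, 1, ])), 1e-10)
})

test_that("rank-deficient nuisance designs are rejected with column names", {
  nt <- 50
  motion <- matrix(rnorm(nt * 6), nt)
  expect_error(nuisance_set(motion, rep(NA_real_, nt), rnorm(nt), rnorm(nt)),
               "finite")
  ns <- nuisance_set(motion, rep(0, nt), rnorm(nt), rnorm(nt))
  g <- template_grid(c(2, 1, 1), 3)
  s <- make_series(rnorm(nt), g)
  expect_error(regress_nuisance(s, ns), "csf")
})

test_that("Gaussian smoothing matches the analytic separable kernel", {
  g <- template_grid(c(15, 15, 15), 3)
  delta <- array(0, dim = g$shape); delta[8, 8, 8] <- 1
  sm <- smooth_gaussian(delta, 4, g)
  expect_equal(sum(sm), 1, tolerance = 1e-6)      # unit mass
  sigma <- 4 / (2 * sqrt(2 * log(2))) / 3
  r <- max(1, ceiling(4 * sigma))
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  oracle <- outer(outer(k1, k1), k1)
  got <- sm[(8 - r):(8 + r), (8 - r):(8 + r), (8 - r):(8 + r)]
  expect_equal(got, oracle, tolerance = 1e-10)
  # constant volumes are unchanged away from the array border
  const <- array(2.5, dim = g$shape)
  smc <- smooth_gaussian(const, 4, g)
  inner <- smc[(1 + r):(15 - r), (1 + r):(15 - r), (1 + r):(15 - r)]
  expect_lt(max(abs(inner - 2.5)), 1e-10)
  # mask-aware renormalisation keeps a constant exactly constant in-mask
  mask <- array(FALSE, dim = g$shape); mask[4:12, 4:12, 4:12] <- TRUE
  smm <- smooth_gaussian(const, 4, g, mask = mask)
  expect_lt(max(abs(smm[mask] - 2.5)), 1e-10)
  expect_identical(smooth_gaussian(const, 0, g), const)
  expect_error(smooth_gaussian(const, -1, g), "non-negative")
})

test_that("branch pipelines follow the metric-order contract", {
  tpl <- small_template()
  spec <- cohort_spec(n_per_group = c(pd = 1, dip = 1, control = 1),
                      n_timepoints = 80, seed = 13)
  sb <- simulate_subject_bold(spec, tpl, 1)
  s <- discard_initial(sb$bold)
  reho_in <- preprocess_branch(s, sb$motion, tpl$masks, "reho")
  # ReHo branch output is band-limited: re-filtering changes nothing
  expect_equal(bandpass_ideal(reho_in)$data, reho_in$data, tolerance = 1e-8)
  alff_in <- preprocess_branch(s, sb$motion, tpl$masks, "alff")
  # ALFF branch is NOT band-limited (the band lives inside the metric)
  expect_gt(mean(abs(bandpass_ideal(alff_in)$data - alff_in$data)), 1e-6)
  # literal processing order is available and differs
  lit <- preprocess_branch(s, sb$motion, tpl$masks, "alff", order = "literal")
  expect_gt(mean(abs(lit$data - alff_in$data)), 1e-8)
})
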