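null_design <- function(n_per_group, seed) {
  set.seed(seed)
  data.frame(
    subject = sprintf("s%02d", seq_len(2 * n_per_group)),
    group = rep(c("pd", "control"), each = n_per_group),
    age = rnorm(2 * n_per_group, 69, 7),
    sex = rbinom(2 * n_per_group, 1, 0.3),
    education = rnorm(2 * n_per_group, 9, 4),
    mmse = rnorm(2 * n_per_group, 27, 2),
    stringsAsFactors = FALSE
  )
}

test_that("contrast t-values agree with the normal-equations oracle", {
  g <- template_grid(c(10, 10, 1), 3)
  mask <- array(TRUE, dim = g$shape)
  d <- null_design(10, 1)
  set.seed(2)
  maps <- matrix(rnorm(100 * 20), 100, 20)
  res <- voxelwise_contrast(maps, d, c("pd", "control"), mask, g)
  X <- cbind(1, as.numeric(d$group == "pd"),
             d$age, d$sex, d$education, d$mmse)
  for (v in c(1, 37, 100)) {
    o <- oracle_ols(X, maps[v, ])
    expect_equal(as.numeric(res$t)[v], o$t[2], tolerance = 1e-8)
  }
  expect_identical(res$df, 14L)
})

test_that("null voxel-wise contrasts reject at the nominal rate", {
  g <- template_grid(c(24, 28, 24), 3)
  mask <- array(TRUE, dim = g$shape)
  d <- null_design(20, 3)
  set.seed(4)
  nvox <- prod(g$shape)
  hits <- 0L; total <- 0L
  for (r in 1:8) {
    maps <- matrix(rnorm(nvox * 40), nvox, 40)
    res <- voxelwise_contrast(maps, d, c("pd", "control"), mask, g)
    tc <- qt(1 - 0.005 / 2, res$df)
    hits <- hits + sum(abs(res$t) > tc)
    total <- total + nvox
  }
  ci <- 0.005 + c(-1, 1) * 1.96 * sqrt(0.005 * 0.995 / total)
  expect_gt(hits / total, ci[1])
  expect_lt(hits / total, ci[2])
})

test_that("an implanted shift is detected and covariate signal is absorbed", {
  g <- template_grid(c(8, 8, 8), 3)
  mask <- array(TRUE, dim = g$shape)
  region <- 1:64                           # first 64 voxels
  detected <- 0L
  for (r in 1:20) {
    d <- null_design(20, 100 + r)
    set.seed(200 + r)
    maps <- matrix(rnorm(512 * 40), 512, 40)
    maps[region, d$group == "pd"] <- maps[region, d$group == "pd"] + 2
    res <- voxelwise_contrast(maps, d, c("pd", "control"), mask, g)
    tc <- qt(1 - 0.005 / 2, res$df)
    if (mean(res$t[region]) > tc) detected <- detected + 1L
  }
  expect_gte(detected, 19L)
  # metric driven only by a covariate: group t centred on zero
  d <- null_design(30, 7)
  set.seed(8)
  maps <- matrix(0.1 * rep(d$age, each = 512) + rnorm(512 * 60), 512, 60)
  res <- voxelwise_contrast(maps, d, c("pd", "control"), mask, g)
  expect_lt(abs(mean(res$t)), 0.15)
})

test_that("contrast validation catches degenerate designs", {
  g <- template_grid(c(2, 2, 1), 3)
  mask <- array(TRUE, dim = g$shape)
  d <- null_design(5, 5)
  maps <- matrix(rnorm(4 * 10), 4, 10)
  d1 <- d; d1$education <- d1$age          # collinear
  expect_error(voxelwise_contrast(maps, d1, c("pd", "control"), mask, g),
               "collinear")
  d2 <- d[c(1, 2, 6, 7), ]
  expect_error(voxelwise_contrast(maps[, c(1, 2, 6, 7)], d2,
                                  c("pd", "control"), mask, g), "few subjects")
  d3 <- d; d3$group[1:9] <- "control"
  expect_error(voxelwise_contrast(maps, d3, c("pd", "control"), mask, g),
               "2 subjects")
})

test_that("cluster labelling matches the flood-fill oracle incl. connectivity", {
  # two blobs touching only at a corner
  vol <- array(FALSE, dim = c(6, 6, 6))
  vol[2:3, 2:3, 2:3] <- TRUE
  vol[4:5, 4:5, 4:5] <- TRUE
  lab26 <- label_clusters(vol, 26)
  expect_identical(max(lab26), 1L)        # corner contact joins under NN3
  lab6 <- label_clusters(vol, 6)
  expect_identical(max(lab6), 2L)         # face connectivity separates
  expect_identical(sort(unique(tabulate(lab6[lab6 > 0]))), 8L)
  lab18 <- label_clusters(vol, 18)
  expect_identical(max(lab18), 2L)        # edge connectivity still separates
  # random fields against the oracle
  set.seed(12)
  for (r in 1:10) {
    v <- array(runif(6^3) < 0.2, dim = c(6, 6, 6))
    for (conn in c(6L, 18L, 26L)) {
      lab <- label_clusters(v, conn)
      expect_identical(max(c(0L, tabulate(lab[lab > 0]))),
                       oracle_max_cluster(v, conn))
      expect_identical(sum(lab > 0), sum(v))
    }
  }
  expect_error(label_clusters(vol, 5), "connectivity")
})

test_that("extent threshold: alpha 1 gives k = 1 and fwhm grows k monotonically", {
  g <- template_grid(c(12, 12, 12), 3)
  mask <- array(TRUE, dim = g$shape)
  k1 <- cluster_extent_threshold(mask, g, 0, p_voxel = 0.005, alpha = 1,
                                 n_iter = 200, seed = 1)
  expect_identical(k1$k_crit, 1L)
  ks <- vapply(c(0, 4, 8), function(fw) {
    median(vapply(1:3, function(s) {
      cluster_extent_threshold(mask, g, fw, p_voxel = 0.01, alpha = 0.05,
                               n_iter = 300, seed = s)$k_crit
    }, integer(1)))
  }, numeric(1))
  expect_true(all(diff(ks) >= 0))
  expect_error(cluster_extent_threshold(mask, g, 0, alpha = 1e-4, n_iter = 100),
               "n_iter")
})

test_that("cluster-extent application keeps only big-enough same-sign blobs", {
  g <- template_grid(c(10, 10, 10), 3)
  mask <- array(TRUE, dim = g$shape)
  tvol <- array(0, dim = g$shape)
  tvol[2:6, 2:6, 2:3] <- 10               # 50-voxel positive blob
  contrast <- list(t = tvol, df = 40L, mask = mask, grid = g)
  r40 <- apply_cluster_threshold(contrast, 0.005, k_crit = 40)
  expect_identical(nrow(r40$clusters), 1L)
  expect_identical(r40$clusters$size, 50L)
  expect_identical(r40$clusters$sign, 1)
  expect_identical(sum(r40$labels > 0), 50L)
  r51 <- apply_cluster_threshold(contrast, 0.005, k_crit = 51)
  expect_identical(nrow(r51$clusters), 0L)
  expect_true(all(r51$labels == 0L))
  # peak location is reported in mm
  pk <- which(tvol == max(tvol), arr.ind = TRUE)[1, , drop = FALSE]
  expect_equal(c(r40$clusters$peak_x_mm, r40$clusters$peak_y_mm,
                 r40$clusters$peak_z_mm),
               as.numeric(vox_to_mm(g, pk)))
})

test_that("conjunction is an idempotent commutative same-sign intersection", {
  g <- template_grid(c(10, 10, 10), 3)
  mask <- array(TRUE, dim = g$shape)
  mk <- function(vox_sign) {
    tvol <- array(0, dim = g$shape)
    for (b in vox_sign) tvol[b$ix, b$iy, b$iz] <- 8 * b$sign
    apply_cluster_threshold(list(t = tvol, df = 40L, mask = mask, grid = g),
                            0.005, k_crit = 5)
  }
  A <- mk(list(list(ix = 2:4, iy = 2:4, iz = 2:4, sign = 1)))
  B <- mk(list(list(ix = 3:6, iy = 2:4, iz = 2:4, sign = 1)))
  AA <- conjunction(A, A)
  expect_identical(AA$labels > 0, A$labels > 0)
  AB <- conjunction(A, B)
  BA <- conjunction(B, A)
  expect_identical(AB$labels > 0, BA$labels > 0)
  # conjunction contained in both inputs
  expect_true(all(which(AB$labels > 0) %in% which(A$labels > 0)))
  expect_true(all(which(AB$labels > 0) %in% which(B$labels > 0)))
  # disjoint inputs -> empty
  C <- mk(list(list(ix = 7:9, iy = 7:9, iz = 7:9, sign = 1)))
  expect_identical(nrow(conjunction(A, C)$clusters), 0L)
  # opposite signs in the overlap -> empty
  D <- mk(list(list(ix = 2:4, iy = 2:4, iz = 2:4, sign = -1)))
  expect_identical(nrow(conjunction(A, D)$clusters), 0L)
  # grid mismatch is an error
  B2 <- B; B2$grid <- template_grid(c(10, 10, 10), 2)
  expect_error(conjunction(A, B2), "grid mismatch")
})
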