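make_maps <- function(n, dim3, seed, add = NULL) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- array(rnorm(prod(dim3)), dim3)
    if (!is.null(add)) m <- m + add[[i]]
    m
  })
}

test_that("voxel-wise regression recovers a planted slope", {
  dim3 <- c(5, 5, 2); mask <- array(TRUE, dim3)
  planted <- 1:10
  slopes <- replicate(100, {
    x <- rnorm(22)
    maps <- lapply(seq_len(22), function(i) {
      m <- array(rnorm(prod(dim3)), dim3)
      m[planted] <- m[planted] + 0.5 * x[i]
      m
    })
    mean(voxelwise_regression(maps, x, mask)$beta[planted])
  })
  expect_gte(mean(slopes), 0.4)
  expect_lte(mean(slopes), 0.6)
})

test_that("pure-noise maps give the nominal suprathreshold voxel rate", {
  dim3 <- c(20, 20, 10); mask <- array(TRUE, dim3)   # 4000 voxels
  frac <- replicate(15, {
    maps <- make_maps(20, dim3, seed = sample.int(1e6, 1))
    x <- rnorm(20)
    stat <- voxelwise_regression(maps, x, mask)
    mean(abs(stat$z[mask]) > 2.326)
  })
  p_nom <- 2 * pnorm(2.326, lower.tail = FALSE)
  tol <- qnorm(0.995) * sqrt(p_nom * (1 - p_nom) / (15 * 4000))
  expect_lt(abs(mean(frac) - p_nom), tol + 0.001)
})

test_that("orthogonal nuisance covariates do not alter the interest estimate", {
  set.seed(3)
  n <- 24
  x <- rnorm(n)
  nuis <- cbind(age = rnorm(n), gender = rbinom(n, 1, 0.5))
  # orthogonalize the regressor of interest against the nuisance space
  x <- resid(lm.fit(cbind(1, nuis), x))
  dim3 <- c(4, 4, 2); mask <- array(TRUE, dim3)
  maps <- make_maps(n, dim3, seed = 4)
  with_n <- voxelwise_regression(maps, x, mask, nuisance = nuis)
  without <- voxelwise_regression(maps, x, mask)
  expect_lt(max(abs(with_n$beta - without$beta)), 1e-8)
  # affine rescaling of nuisance columns leaves z untouched
  rescaled <- voxelwise_regression(maps, x, mask,
                                   nuisance = cbind(10 * nuis[, 1] - 3,
                                                    2 * nuis[, 2] + 1))
  expect_lt(max(abs(with_n$z - rescaled$z)), 1e-8)
  expect_error(voxelwise_regression(maps, x, mask,
                                    nuisance = cbind(x, x)),
               "rank deficient")
})

test_that("two-sample maps are null for identical groups and antisymmetric", {
  dim3 <- c(4, 4, 3); mask <- array(TRUE, dim3)
  base <- make_maps(8, dim3, seed = 7)
  maps <- c(base, base)      # the same maps, relabeled
  g <- rep(c("a", "b"), each = 8)
  z0 <- voxelwise_two_sample(maps, g, mask)$z
  expect_lt(max(abs(z0)), 1e-10)
  maps2 <- make_maps(16, dim3, seed = 8)
  za <- voxelwise_two_sample(maps2, g, mask)$z
  zb <- voxelwise_two_sample(maps2, rev(g), mask)$z
  expect_equal(za, -zb, tolerance = 1e-10)
  expect_error(voxelwise_two_sample(maps2[1:3], c("a", "a", "b"), mask),
               "at least 2")
})

test_that("a planted group difference is detected with the expected power", {
  dim3 <- c(8, 5, 5); mask <- array(TRUE, dim3)   # 200 voxels
  region <- 1:50
  d <- 1.5; n <- 11
  # noncentral-t oracle for the per-voxel mean z
  hits <- replicate(100, {
    eff <- array(0, dim3); eff[region] <- d
    maps <- c(make_maps(n, dim3, seed = sample.int(1e6, 1),
                        add = rep(list(eff), n)),
              make_maps(n, dim3, seed = sample.int(1e6, 1)))
    stat <- voxelwise_two_sample(maps, rep(c("hi", "lo"), each = n), mask)
    mean(stat$z[region]) > 2
  })
  expect_gte(mean(hits), 0.8)
})

test_that("t-to-z conversion is monotone, sign-preserving and exact at zero", {
  t_vals <- c(-5, -1.2, 0, 0.3, 2, 8, 30)
  z <- cardiohub:::t_to_z(t_vals, df = 18)
  expect_identical(z[t_vals == 0], 0)
  expect_true(all(diff(z) > 0))
  expect_identical(sign(z), sign(t_vals))
  # quantile matching against the exact tail probability
  expect_equal(pnorm(z[2]), pt(t_vals[2], 18), tolerance = 1e-12)
})

test_that("Monte Carlo thresholds behave monotonically and reproducibly", {
  mask <- array(TRUE, c(12, 12, 8))
  thr_a <- monte_carlo_cluster_threshold(mask, 3, 6, n_iterations = 300,
                                         seed = 5)
  thr_b <- monte_carlo_cluster_threshold(mask, 3, 6, n_iterations = 300,
                                         seed = 5)
  expect_identical(thr_a$critical_size, thr_b$critical_size)
  expect_identical(thr_a$critical_mass, thr_b$critical_mass)
  thr_strict <- monte_carlo_cluster_threshold(mask, 3, 6, z_form = 3.09,
                                              n_iterations = 300, seed = 5)
  expect_lte(thr_strict$critical_size, thr_a$critical_size)
  thr_rough <- monte_carlo_cluster_threshold(mask, 3, 0, n_iterations = 300,
                                             seed = 5)
  expect_lt(thr_rough$critical_size, thr_a$critical_size)
  expect_error(monte_carlo_cluster_threshold(mask, 3, 6, z_form = -1),
               "z_form")
  expect_error(monte_carlo_cluster_threshold(mask, 3, 6, n_iterations = 50),
               "200")
})

test_that("cluster tables honour critical values, signs and connectivity", {
  dim3 <- c(10, 10, 6); mask <- array(TRUE, dim3)
  z <- array(0, dim3)
  z[2:5, 2:6, 2:6] <- 3            # 100-voxel positive cluster
  stat <- structure(list(z = z, df = 20, mask = mask), class = "stat_map")
  thr <- structure(list(z_form = 2.326, alpha = 0.05, critical_size = 50,
                        critical_mass = Inf, connectivity = 26,
                        rule = "either"), class = "cluster_threshold")
  tab <- apply_cluster_threshold(stat, thr)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$size, 100)
  expect_true(tab$significant)
  vox <- cluster_voxels(stat, tab, thr$z_form)
  expect_length(vox[[1]], 100)
  # all-zero map: empty table
  stat0 <- structure(list(z = array(0, dim3), df = 20, mask = mask),
                     class = "stat_map")
  expect_equal(nrow(apply_cluster_threshold(stat0, thr)), 0)
  # two diagonally touching blobs: one cluster under 26, two under 6
  z2 <- array(0, dim3)
  z2[2, 2, 2] <- 3; z2[3, 3, 3] <- 3
  stat2 <- structure(list(z = z2, df = 20, mask = mask), class = "stat_map")
  t26 <- cardiohub:::.cluster_table(stat2, 2.326, 26)
  t6 <- cardiohub:::.cluster_table(stat2, 2.326, 6)
  expect_equal(nrow(t26), 1)
  expect_equal(nrow(t6), 2)
  # negative clusters carry their sign
  zs <- array(0, dim3); zs[6:8, 6:8, 2:4] <- -4
  ts <- cardiohub:::.cluster_table(
    structure(list(z = zs, df = 20, mask = mask), class = "stat_map"),
    2.326, 26)
  expect_equal(ts$sign, -1)
  expect_lt(ts$peak_z, 0)
})

test_that("uncorrected maps use the p = .001 quantile and the extent rule", {
  dim3 <- c(8, 8, 4); mask <- array(TRUE, dim3)
  z <- array(0, dim3)
  z[1:3, 1:3, 1] <- 3.2            # 9 voxels above 3.0902
  stat <- structure(list(z = z, df = 20, mask = mask), class = "stat_map")
  expect_equal(nrow(uncorrected_map(stat, 0.001, extent_voxels = 10)), 0)
  tab <- uncorrected_map(stat, 0.001, extent_voxels = 1)
  expect_equal(tab$size, 9)
  # voxels between 3.05 and 3.0902 are subthreshold at p = .001
  z2 <- array(0, dim3); z2[1, 1, 1] <- 3.05; z2[5, 5, 2] <- 3.12
  stat2 <- structure(list(z = z2, df = 20, mask = mask), class = "stat_map")
  tab2 <- uncorrected_map(stat2, 0.001, extent_voxels = 1)
  expect_equal(nrow(tab2), 1)
  expect_equal(tab2$peak_z, 3.12)
})

test_that("single-voxel ROI permutation p matches an independent implementation", {
  set.seed(12)
  n <- 16
  dim3 <- c(3, 3, 2); mask <- array(TRUE, dim3)
  roi <- array(FALSE, dim3); roi[2, 2, 1] <- TRUE
  x <- rnorm(n)
  nuis <- cbind(rnorm(n))
  maps <- make_maps(n, dim3, seed = 13)
  res <- roi_small_volume(maps, x, mask, roi, nuisance = nuis,
                          n_permutations = 600, seed = 77)
  # independent Freedman-Lane oracle on the single ROI voxel
  y <- vapply(maps, function(m) m[2, 2, 1], numeric(1))
  zr <- cbind(1, nuis)
  hz <- zr %*% solve(crossprod(zr)) %*% t(zr)
  fit <- hz %*% y; rs <- y - fit
  tstat <- function(yy) {
    xx <- cbind(1, x, nuis)
    b <- solve(crossprod(xx), crossprod(xx, yy))
    r2 <- yy - xx %*% b
    s2 <- sum(r2^2) / (n - 3)
    b[2] / sqrt(s2 * solve(crossprod(xx))[2, 2])
  }
  obs <- abs(tstat(y))
  set.seed(77)
  perm <- replicate(600, abs(tstat(fit + rs[sample.int(n)])))
  expect_equal(res$p_peak, (1 + sum(perm >= obs)) / 601, tolerance = 1e-12)
  expect_error(roi_small_volume(maps, x, mask, array(FALSE, dim3)), "empty")
  expect_error(roi_small_volume(maps, x, mask, roi, n_permutations = 100),
               "500")
})
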