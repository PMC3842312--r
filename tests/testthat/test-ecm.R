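test_that("high-pass filter removes drifts and passes fast components", {
  nt <- 300; tr <- 2
  mk <- function(y) volume_series(array(rep(y, each = 8), c(2, 2, 2, nt)),
                                  3, tr)
  # constant series: zero after mean removal
  out <- highpass_filter(mk(rep(3.7, nt)))
  expect_lt(max(abs(out$data)), 1e-9)
  # slow tone (1/200 Hz, below the 1/90 cutoff): attenuated to <= 10 %
  tone <- function(f) sin(2 * pi * f * (0:(nt - 1)) * tr + 0.7)
  slow <- highpass_filter(mk(tone(1 / 200)))
  expect_lte(sd(slow$data[1, 1, 1, ]) / sd(tone(1 / 200)), 0.10)
  # fast tone (0.05 Hz): passes >= 95 %
  fast <- highpass_filter(mk(tone(0.05)))
  expect_gte(sd(fast$data[1, 1, 1, ]) / sd(tone(0.05)), 0.95)
  # cutoff at/above Nyquist errors
  expect_error(highpass_filter(mk(tone(0.05)),
                               preprocess_config(highpass_cutoff_hz = 0.25)),
               "Nyquist")
})

test_that("Gaussian smoothing preserves constants, mass, and the half-maximum radius", {
  const <- array(2.5, c(10, 10, 8))
  expect_lt(max(abs(smooth_volume(const, 6, 3) - 2.5)), 1e-9)
  # delta impulse on a 0.5 mm grid: half maximum at 3 mm for FWHM 6 mm
  g <- array(0, c(81, 81, 81))
  g[41, 41, 41] <- 1
  sm <- smooth_volume(g, 6, 0.5)
  expect_equal(sm[41 + 6, 41, 41] / sm[41, 41, 41], 0.5, tolerance = 0.02)
  # mass conserved away from boundaries
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_error(smooth_volume(g, -1, 1), "fwhm")
})

test_that("similarity transform maps correlations into [0, 1] as specified", {
  t_axis <- seq_len(40)
  y <- cbind(sin(t_axis), sin(t_axis), -sin(t_axis), rnorm(40))
  s <- similarity_matrix(y)
  expect_equal(s[1, 2], 1)            # perfect correlation: g(1) = 1
  expect_equal(s[1, 3], 0)            # anti-correlation: g(-1) = 0
  expect_true(all(diag(s) == 0))
  expect_true(all(s >= 0 & s <= 1))
  sr <- similarity_matrix(y, transform = "rectify")
  expect_equal(sr[1, 3], 0)
  expect_error(similarity_matrix(cbind(y, 1)), "zero-variance")
})

test_that("matrix-free products agree with the dense similarity matrix", {
  vs <- small_series(c(10, 5, 4), nt = 50, seed = 2)     # 200 voxels
  s <- similarity_matrix(vs)
  cmat <- cardiohub:::.standardize_rows(vs)
  op <- cardiohub:::.ecm_operator(cmat)
  set.seed(1)
  for (i in 1:3) {
    v <- runif(200)
    dense <- as.numeric(s %*% v)
    free <- 0.5 * (as.numeric(cmat %*% crossprod(cmat, v)) + sum(v)) - v
    expect_lt(max(abs(dense - free)), 1e-10)
  }
})

test_that("power iteration matches dense eigendecompositions", {
  # 3-voxel toy graph against a brute-force eigensolver
  s3 <- matrix(c(0, .9, .1, .9, 0, .1, .1, .1, 0), 3)
  v3 <- eigenvector_centrality(s3)$vector
  ev3 <- eigen(s3)$vectors[, 1]
  ev3 <- abs(ev3) / sqrt(sum(ev3^2))
  expect_lt(max(abs(v3 - ev3)), 1e-8)
  # all-identical series: uniform map 1/sqrt(V)
  ones <- matrix(1, 12, 12); diag(ones) <- 0
  vu <- eigenvector_centrality(ones)$vector
  expect_equal(vu, rep(1 / sqrt(12), 12), tolerance = 1e-9)
  # star graph: the hub has the strictly largest centrality
  k <- 6
  star <- matrix(0, k + 1, k + 1)
  star[1, 2:(k + 1)] <- star[2:(k + 1), 1] <- 0.8
  vs <- eigenvector_centrality(star)$vector
  expect_equal(which.max(vs), 1)
  expect_true(all(vs[1] > vs[-1]))
  # closed form: hub/spoke ratio is sqrt(k)
  expect_equal(vs[1] / vs[2], sqrt(k), tolerance = 1e-6)
  expect_error(eigenvector_centrality(s3, max_iter = 2), "did not converge")
  expect_error(eigenvector_centrality(-s3), "nonnegative")
})

test_that("matrix-free and dense session pipelines agree", {
  vs <- small_series(c(8, 6, 5), nt = 60, seed = 3)
  m_free <- session_ecm(vs)
  m_dense <- session_ecm(vs, dense = TRUE)
  expect_lt(max(abs(m_free$values - m_dense$values)), 1e-6)
  expect_equal(sum(m_free$values^2), 1, tolerance = 1e-9)
  expect_true(all(m_free$values >= 0))
})

test_that("session ECM finds a planted hub and is deterministic", {
  p <- bold_gen_params(grid_shape = c(8, 8, 6), n_trials = 6)
  bold <- simulate_bold_cohort(p, traits = 2, seed = 9)
  m <- session_ecm(bold[[1]])
  planted <- c(attr(bold[[1]], "hub_index"), attr(bold[[1]], "network_index"))
  expect_true(which.max(m$values) %in% planted)
  m2 <- session_ecm(bold[[1]])
  expect_identical(m$values, m2$values)
})

test_that("centrality is invariant to volume order and voxel relabeling", {
  vs <- small_series(c(6, 5, 4), nt = 50, seed = 4)
  cfg <- preprocess_config(highpass_cutoff_hz = 1e-6, smooth_fwhm_mm = 0)
  m1 <- session_ecm(vs, cfg)
  shuffled <- vs
  set.seed(7)
  shuffled$data <- vs$data[, , , sample(50)]
  m2 <- session_ecm(shuffled, cfg)
  expect_equal(m1$values, m2$values, tolerance = 1e-9)
  # voxel relabeling: permuting time series permutes the map identically
  y <- matrix(vs$data, 120, 50)
  perm <- sample(120)
  s_orig <- similarity_matrix(t(y))
  s_perm <- similarity_matrix(t(y[perm, ]))
  v_orig <- eigenvector_centrality(s_orig)$vector
  v_perm <- eigenvector_centrality(s_perm)$vector
  expect_equal(v_perm, v_orig[perm], tolerance = 1e-7)
})

test_that("strengthening a voxel's coupling strictly increases its centrality", {
  base <- matrix(0.3, 5, 5); diag(base) <- 0
  v0 <- eigenvector_centrality(base)$vector
  up <- base
  up[1, 2] <- up[2, 1] <- 0.9
  v1 <- eigenvector_centrality(up)$vector
  expect_gt(v1[1] / sum(v1), v0[1] / sum(v0))
})

test_that("per-condition ECMs follow the epoch design", {
  p <- bold_gen_params(grid_shape = c(6, 6, 4))
  bold <- simulate_bold_cohort(p, traits = 1, seed = 12)
  maps <- condition_ecms(bold[[1]])
  expect_setequal(names(maps), c("joy", "fear", "neutral"))
  for (m in maps) {
    expect_equal(attr(m, "n_epochs"), 16)
    expect_equal(sum(m$values^2), 1, tolerance = 1e-9)
  }
  # all epochs identical: the averaged map equals a single epoch map
  d <- c(4, 4, 3); nt <- 30
  set.seed(5)
  block <- array(rnorm(prod(d) * 15), c(d, 15))
  dat <- array(c(block, block), c(d, nt))
  vs <- volume_series(dat, 3, 2,
                      condition_labels = rep(c("joy", "joy"), each = 15))
  cfg <- preprocess_config(highpass_cutoff_hz = 1e-6, smooth_fwhm_mm = 0)
  avg <- condition_ecms(vs, cfg, conditions = "joy")
  single <- cardiohub:::.ecm_from_series(
    smooth_volume(highpass_filter(vs, cfg), cfg = cfg), vols = 1:15)
  expect_equal(avg$joy$values, single$values, tolerance = 1e-7)
  # epochs shorter than the minimum are rejected, naming the epoch
  vs_short <- volume_series(dat, 3, 2,
                            condition_labels = c(rep("joy", 8),
                                                 rep("rest", 7),
                                                 rep("fear", 15)))
  expect_error(condition_ecms(vs_short, cfg), "too short")
})

test_that("a hub planted only in one condition's epochs is condition specific", {
  d <- c(6, 6, 4); nvox <- prod(d)
  labels <- rep(rep(c("joy", "neutral"), each = 15), 8)   # 8 epochs each
  nt <- length(labels)
  hub <- 43
  net <- c(44, 45, 50, 56, 62, 75, 80)
  hits <- 0
  for (run in 1:10) {
    set.seed(100 + run)
    dat <- matrix(rnorm(nvox * nt), nvox, nt)
    latent <- rnorm(nt)
    joy_vols <- labels == "joy"
    dat[hub, joy_vols] <- dat[hub, joy_vols] + 2.5 * latent[joy_vols]
    for (v in net) dat[v, joy_vols] <- dat[v, joy_vols] + 2.0 * latent[joy_vols]
    vs <- volume_series(array(dat, c(d, nt)), 3, 2, condition_labels = labels)
    # mean-only temporal filtering: epoch-wise centring then makes the
    # neutral epochs truly signal-free
    maps <- condition_ecms(vs, preprocess_config(highpass_cutoff_hz = 1e-6,
                                                 smooth_fwhm_mm = 0))
    ok_joy <- which.max(maps$joy$values) %in% c(hub, net)
    ok_neu <- !(which.max(maps$neutral$values) %in% c(hub, net))
    hits <- hits + (ok_joy && ok_neu)
  }
  expect_gte(hits / 10, 0.8)
})
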