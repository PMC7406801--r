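test_that("FA and MD match closed forms and reject invalid tensors", {
  r <- compute_fa_md(rbind(c(1, 1, 1), c(1, 0, 0), c(2, 1, 1)))
  expect_equal(r$fa, c(0, 1, sqrt(1 / 6)), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(r$md, c(1, 1 / 3, 4 / 3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(compute_fa_md(rbind(c(0, 0, 0)))$fa, 0, ignore_attr = TRUE)
  expect_error(compute_fa_md(rbind(c(1, -0.1, -0.2))), "negative eigenvalue")
  expect_error(compute_fa_md(rbind(c(1, 2, 3))), "sorted")
})

test_that("FA is scale-invariant and bounded on random tensors", {
  set.seed(1)
  lam <- t(apply(matrix(stats::rexp(3000), ncol = 3), 1, sort, decreasing = TRUE))
  fa <- compute_fa_md(lam)$fa
  expect_true(all(fa >= 0 & fa <= 1))
  fa_scaled <- compute_fa_md(lam * 7.3)$fa
  expect_equal(fa, fa_scaled, tolerance = 1e-12)
})

test_that("detrending annihilates constants and ramps, band-pass keeps in-band signal", {
  Tn <- 110
  mk_vol <- function(series) array(rep(series, each = 8), c(2, 2, 2, Tn))
  con <- preprocess_timeseries(mk_vol(rep(5, Tn)), tr_seconds = 2, drop_initial = 10)
  expect_lt(max(abs(con)), 1e-10)
  ramp <- preprocess_timeseries(mk_vol(seq_len(Tn)), tr_seconds = 2, drop_initial = 10)
  expect_lt(max(abs(ramp)), 1e-10)
  # 0.05 Hz sinusoid, band (0.01, 0.08), TR = 2: >= 95% variance retained
  s <- sin(2 * pi * 0.05 * 2 * seq_len(Tn))
  filt <- preprocess_timeseries(mk_vol(s), tr_seconds = 2, drop_initial = 10,
                                band_hz = c(0.01, 0.08))
  raw <- preprocess_timeseries(mk_vol(s), tr_seconds = 2, drop_initial = 10)
  expect_gt(sum(filt[1, 1, 1, ]^2) / sum(raw[1, 1, 1, ]^2), 0.95)
  expect_error(preprocess_timeseries(mk_vol(s), tr_seconds = 2, band_hz = c(0.01, 0.5)),
               "Nyquist")
})

test_that("ALFF/fALFF match spectral oracles", {
  Tn <- 200
  vol <- array(0, c(2, 2, 1, Tn))
  s <- sin(2 * pi * 0.05 * 2 * seq_len(Tn))        # exactly on a DFT bin
  vol[1, 1, 1, ] <- s
  expect_warning(r <- compute_alff_falff(vol, tr_seconds = 2),
                 "zero total amplitude")
  expect_equal(r$alff[2, 2, 1], 0)
  expect_equal(r$falff[2, 2, 1], 0)
  expect_gte(r$falff[1, 1, 1], 0.99)
  # ALFF linearity: scaling the series scales ALFF, leaves fALFF unchanged
  vol2 <- vol * -3
  expect_warning(r2 <- compute_alff_falff(vol2, tr_seconds = 2), "zero")
  expect_equal(r2$alff[1, 1, 1], 3 * r$alff[1, 1, 1], tolerance = 1e-12)
  expect_equal(r2$falff[1, 1, 1], r$falff[1, 1, 1], tolerance = 1e-12)
})

test_that("white-noise fALFF approximates the in-band bin fraction", {
  set.seed(3)
  Tn <- 200; tr <- 2
  vol <- array(stats::rnorm(6 * 6 * 2 * Tn), c(6, 6, 2, Tn))
  r <- compute_alff_falff(vol, tr_seconds = tr)
  f <- (1:(Tn / 2)) / (Tn * tr)
  frac <- sum(f >= 0.01 & f <= 0.08) / sum(f > 0 & f <= 0.25)
  expect_lt(abs(mean(r$falff) - frac), 0.05)
})

test_that("Kendall's W matches the hand-worked example and bounds", {
  expect_equal(kendall_w(rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1))), 1 / 9,
               tolerance = 1e-12)
  expect_equal(kendall_w(matrix(rep(1:10, 5), 5, byrow = TRUE)), 1)
  set.seed(4)
  w <- replicate(200, kendall_w(matrix(stats::rnorm(3 * 20), 3)))
  expect_true(all(w >= 0 & w <= 1))
})

test_that("ReHo agrees with voxel-wise Kendall's W and handles edge cases", {
  set.seed(5)
  vol <- array(stats::rnorm(5 * 5 * 5 * 30), c(5, 5, 5, 30))
  w <- compute_reho(vol, neighborhood = 27)
  # independent oracle at one interior voxel: gather the 27 series directly
  vox <- c(3, 3, 3)
  series <- matrix(NA_real_, 27, 30)
  k <- 0
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    k <- k + 1
    series[k, ] <- vol[vox[1] + dx, vox[2] + dy, vox[3] + dz, ]
  }
  expect_equal(w[3, 3, 3], kendall_w(series), tolerance = 1e-12)
  # boundary voxels zeroed
  expect_true(all(w[1, , ] == 0) && all(w[, , 5] == 0))
  # perfect concordance: identical series everywhere
  same <- array(rep(sin(seq_len(30)), each = 27), c(3, 3, 3, 30))
  w1 <- compute_reho(same)
  expect_equal(w1[2, 2, 2], 1, tolerance = 1e-12)
  # fully constant neighborhood -> 0 with warning
  expect_warning(w0 <- compute_reho(array(1, c(3, 3, 3, 25))), "constant")
  expect_equal(w0[2, 2, 2], 0)
})

test_that("ReHo null level is small and invariant to monotone transforms", {
  set.seed(6)
  vol <- array(stats::rnorm(4 * 4 * 4 * 140), c(4, 4, 4, 140))
  w <- compute_reho(vol)
  msk <- attr(w, "interior_mask")
  expect_lt(mean(w[msk]), 0.1)
  wt <- compute_reho(exp(vol * 2) + 1)  # strictly monotone transform
  expect_equal(w[msk], wt[msk], tolerance = 1e-12)
})

test_that("Gaussian smoothing preserves constants and mass locally", {
  v <- array(1, c(6, 6, 6))
  expect_equal(gaussian_smooth3d(v, 1.2), v, tolerance = 1e-12)
  pt <- array(0, c(9, 9, 9)); pt[5, 5, 5] <- 1
  sm <- gaussian_smooth3d(pt, 1)
  expect_equal(sum(sm), 1, tolerance = 0.01)   # truncated kernel, near-conserving
  expect_true(sm[5, 5, 5] < 1 && sm[4, 5, 5] > 0)
})
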