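test_that("bandpass_filter passes in-band and kills out-of-band power", {
  tt <- seq_len(64); tr <- 2
  mk <- function(f) {
    sig <- sin(2 * pi * f * tt * tr)
    arr <- array(rep(sig, each = 8), c(2, 2, 2, 64))
    arr <- aperm(array(sig, c(64, 2, 2, 2)), c(2, 3, 4, 1))
    bold_run(arr, tr)
  }
  inband <- bandpass_filter(mk(0.04), 0.01, 0.08)
  s <- inband$values[1, 1, 1, ]
  expect_gt(sd(s) / sd(sin(2 * pi * 0.04 * tt * tr)), 0.95)
  outband <- bandpass_filter(mk(0.2), 0.01, 0.08)
  expect_lt(sd(outband$values[1, 1, 1, ]) /
              sd(sin(2 * pi * 0.2 * tt * tr)), 0.05)
  # constant series -> all-zero output (DC removed)
  const <- bold_run(array(3, c(2, 2, 2, 16)), tr)
  expect_equal(max(abs(bandpass_filter(const, 0.01, 0.08)$values)), 0,
               tolerance = 1e-10)
  # FFT oracle: result equals explicit spectral masking
  set.seed(21)
  y <- rnorm(32)
  run1 <- bold_run(array(y, c(1, 1, 1, 32)), tr)
  f <- (0:31) / (32 * tr); f <- pmin(f, 1 / tr - f)
  keep <- f >= 0.01 & f <= 0.08 & f > 0
  expected <- Re(fft(replace(fft(y), !keep, 0), inverse = TRUE)) / 32
  expect_equal(as.vector(bandpass_filter(run1, 0.01, 0.08)$values),
               expected, tolerance = 1e-10)
  expect_error(bandpass_filter(mk(0.04), 0.01, 0.5), "Nyquist")
})

test_that("regress_nuisance residuals match the normal-equations oracle", {
  set.seed(22)
  Tn <- 30
  arr <- array(rnorm(8 * Tn), c(2, 2, 2, Tn))
  run <- bold_run(arr, 2)
  reg <- matrix(rnorm(Tn * 3), Tn)
  out <- regress_nuisance(run, reg)
  for (v in list(c(1, 1, 1), c(2, 2, 2))) {
    y <- arr[v[1], v[2], v[3], ]
    expect_equal(out$values[v[1], v[2], v[3], ],
                 as.vector(oracle_ls_residuals(y, reg)),
                 tolerance = 1e-10)
  }
  # residuals orthogonal to every regressor column
  res <- out$values[1, 2, 1, ]
  for (k in 1:3)
    expect_lt(abs(sum(res * reg[, k])),
              1e-8 * sqrt(sum(res^2) * sum(reg[, k]^2)))
  # intercept only -> demeaned series
  dm <- regress_nuisance(run, matrix(0, Tn, 0))
  expect_equal(dm$values[1, 1, 1, ], arr[1, 1, 1, ] - mean(arr[1, 1, 1, ]),
               tolerance = 1e-10)
  # series equal to a regressor -> zero residual
  arr2 <- arr; arr2[1, 1, 1, ] <- reg[, 2]
  out2 <- regress_nuisance(bold_run(arr2, 2), reg)
  expect_equal(max(abs(out2$values[1, 1, 1, ])), 0, tolerance = 1e-10)
  # rank deficiency rejected
  expect_error(regress_nuisance(run, cbind(reg, reg[, 1])),
               "rank deficient")
})

test_that("compute_reho matches the brute-force rank oracle", {
  set.seed(23)
  for (rep in 1:5) {
    run <- random_cube_run(20)
    mask <- array(TRUE, c(3, 3, 3))
    W <- compute_reho(run, mask, 26)
    series <- lapply(1:27, function(i) {
      co <- arrayInd(i, c(3, 3, 3))
      run$values[co[1], co[2], co[3], ]
    })
    expect_equal(W$values[2, 2, 2], oracle_kendall_w(series),
                 tolerance = 1e-12)
  }
  # all series identical -> W = 1 at the center (27 full neighbors)
  sig <- rnorm(20)
  same <- bold_run(array(rep(sig, each = 27), c(3, 3, 3, 20)), 2)
  same$values[] <- rep(sig, each = 27)
  W1 <- compute_reho(same, array(TRUE, c(3, 3, 3)))
  expect_equal(W1$values[2, 2, 2], 1, tolerance = 1e-12)
  # K = 2 anti-concordant pair: W = 0  (two-voxel mask)
  m2 <- array(FALSE, c(3, 3, 3)); m2[1, 1, 1] <- m2[2, 1, 1] <- TRUE
  arr <- array(0, c(3, 3, 3, 10))
  arr[1, 1, 1, ] <- 1:10; arr[2, 1, 1, ] <- 10:1
  W0 <- compute_reho(bold_run(arr, 2), m2)
  expect_equal(W0$values[1, 1, 1], 0, tolerance = 1e-12)
  expect_true(all(W$values[mask] >= 0 & W$values[mask] <= 1))
})

test_that("ReHo is invariant to monotone transforms and time relabeling", {
  set.seed(24)
  run <- random_cube_run(15)
  mask <- array(TRUE, c(3, 3, 3))
  W <- compute_reho(run, mask)
  # strictly increasing transform of every series leaves ranks alone
  runt <- bold_run(exp(run$values / 2) + run$values^3, 2)
  expect_equal(compute_reho(runt, mask)$values, W$values,
               tolerance = 1e-12)
  # identical permutation of time points across all voxels
  perm <- sample(15)
  runp <- bold_run(run$values[, , , perm], 2)
  expect_equal(compute_reho(runp, mask)$values, W$values,
               tolerance = 1e-12)
})

test_that("isolated voxels are flagged undefined and dropped", {
  m <- array(FALSE, c(5, 5, 5))
  m[1, 1, 1] <- TRUE            # no neighbor anywhere
  m[4, 4, 4] <- m[5, 4, 4] <- TRUE
  arr <- array(rnorm(125 * 12), c(5, 5, 5, 12))
  expect_warning(W <- compute_reho(bold_run(arr, 2), m), "undefined")
  expect_false(W$mask[1, 1, 1])
  expect_true(W$mask[4, 4, 4])
  expect_equal(attr(W, "undefined"),
               which(array(seq_len(125), c(5, 5, 5)) == 1))
})

test_that("standardize_reho normalizes the in-mask mean to 1", {
  m <- array(FALSE, c(3, 3, 3)); m[1:2, 1, 1] <- TRUE
  v <- array(0, c(3, 3, 3)); v[1, 1, 1] <- 1; v[2, 1, 1] <- 3
  out <- standardize_reho(volume_map(v, m))
  expect_equal(out$values[1:2, 1, 1], c(0.5, 1.5))
  # constant map -> constant 1; any map -> mean exactly 1
  vc <- array(0.4, c(3, 3, 3))
  outc <- standardize_reho(volume_map(vc, m))
  expect_equal(unique(outc$values[m]), 1)
  set.seed(25)
  vr <- array(abs(rnorm(27)) + 0.1, c(3, 3, 3))
  expect_equal(mean(standardize_reho(volume_map(vr, m))$values[m]), 1,
               tolerance = 1e-12)
  v0 <- array(0, c(3, 3, 3))
  expect_error(standardize_reho(volume_map(v0, m)), "positive")
})

test_that("smooth_volume is identity at fwhm 0, preserves constants, and
           matches the analytic Gaussian for a delta spike", {
  mask <- array(TRUE, c(15, 15, 15))
  v <- array(0, c(15, 15, 15)); v[8, 8, 8] <- 1
  vol <- volume_map(v, mask, voxel_size_mm = 1)
  expect_identical(smooth_volume(vol, 0)$values, v)
  vc <- volume_map(array(2.5, c(15, 15, 15)), mask, voxel_size_mm = 1)
  expect_equal(smooth_volume(vc, 4)$values,
               array(2.5, c(15, 15, 15)), tolerance = 1e-10)
  sm <- smooth_volume(vol, 4)
  sigma <- 4 / (2 * sqrt(2 * log(2)))
  co <- as.matrix(expand.grid(1:15, 1:15, 1:15)) - 8
  analytic <- exp(-rowSums(co^2) / (2 * sigma^2)) /
    (2 * pi * sigma^2)^(3 / 2)
  center_idx <- rowSums(abs(co)) <= 3      # compare near the spike
  rel_err <- abs(as.vector(sm$values)[center_idx] -
                   analytic[center_idx]) / analytic[center_idx]
  expect_lt(max(rel_err), 0.01)
  expect_error(smooth_volume(vol, -1), "nonnegative")
})

test_that("region_timeseries equals the voxel-loop mean", {
  set.seed(26)
  mask <- make_brain_mask(c(8, 8, 8))
  atlas <- make_atlas(mask, 3)
  Tn <- 10
  arr <- array(rnorm(8^3 * Tn), c(8, 8, 8, Tn))
  run <- bold_run(arr, 2)
  ts <- region_timeseries(run, atlas, mask)
  for (r in 1:3) {
    vox <- which(atlas$values == r & mask$mask)
    manual <- rep(0, Tn)
    for (v in vox) {
      co <- arrayInd(v, c(8, 8, 8))
      manual <- manual + arr[co[1], co[2], co[3], ]
    }
    expect_equal(ts[r, ], manual / length(vox), tolerance = 1e-12)
  }
  # single-voxel region returns that voxel's series verbatim
  m1 <- array(FALSE, c(8, 8, 8)); m1[1, 1, 1] <- m1[2, 1, 1] <- TRUE
  a1 <- array(0L, c(8, 8, 8)); a1[1, 1, 1] <- 1L; a1[2, 1, 1] <- 2L
  at <- volume_map(a1, m1)
  ts1 <- region_timeseries(run, at, m1)
  expect_equal(ts1[1, ], arr[1, 1, 1, ])
  # opposite series cancel
  arr[2, 1, 1, ] <- -arr[1, 1, 1, ]
  a2 <- array(0L, c(8, 8, 8)); a2[1, 1, 1] <- a2[2, 1, 1] <- 1L
  ts2 <- region_timeseries(bold_run(arr, 2), volume_map(a2, m1), m1)
  expect_equal(max(abs(ts2[1, ])), 0, tolerance = 1e-12)
  # empty region named in the error
  a3 <- a1; a3[2, 1, 1] <- 3L
  expect_error(region_timeseries(run, volume_map(a3, m1), m1), "2")
})

test_that("fc_matrix applies the Fisher transform with clamping", {
  set.seed(27)
  # closed form: r = 0.5 -> z = 0.5 * log(3)
  t1 <- rnorm(200)
  t2 <- 0.5 * t1 + sqrt(1 - 0.25) * rnorm(200)
  ts <- rbind(t1, t2)
  r <- cor(t1, t2)
  fc <- fc_matrix(ts)
  expect_equal(fc$z_values[1, 2], atanh(r), tolerance = 1e-12)
  expect_equal(atanh(0.5), 0.5 * log(3), tolerance = 1e-12)
  # uncorrelated pair: z near 0; diagonal exactly 0; symmetric
  expect_equal(unname(diag(fc$z_values)), c(0, 0))
  expect_equal(fc$z_values, t(fc$z_values))
  # perfectly correlated rows stay finite through clamping
  ts2 <- rbind(t1, t1 * 2 + 1, t2)
  fc2 <- fc_matrix(ts2)
  expect_true(all(is.finite(fc2$z_values)))
  expect_equal(fc2$z_values[1, 2], atanh(1 - 1e-7))
  # 116 regions -> 6,670 unique pairs
  big <- matrix(rnorm(116 * 10), 116)
  expect_equal(length(edge_vector(fc_matrix(big))), 6670)
  expect_error(fc_matrix(rbind(t1, rep(1, 200))), "zero-variance")
})

test_that("fc_matrix is invariant to positive affine rescaling of rows", {
  set.seed(28)
  ts <- matrix(rnorm(4 * 50), 4)
  z1 <- fc_matrix(ts)$z_values
  ts2 <- ts * c(2, 0.5, 10, 3) + c(-1, 4, 0, 2)
  expect_equal(fc_matrix(ts2)$z_values, z1, tolerance = 1e-10)
})
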