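test_that("sphere masks have the right geometry", {
  aff <- diag(c(3, 3, 3, 1))  # 3 mm isotropic, origin at voxel (0,0,0)
  roi <- list(name = "test", x = 30, y = 30, z = 30, radius = 6)
  mask <- sphere_mask(roi, aff, c(21, 21, 21))
  # independent enumeration: integer offsets with i^2+j^2+k^2 <= (6/3)^2
  offs <- expand.grid(i = -2:2, j = -2:2, k = -2:2)
  expect_equal(sum(mask), sum(offs$i^2 + offs$j^2 + offs$k^2 <= 4))
  expect_equal(sum(mask), 33)

  # radius just under the voxel spacing: only the center voxel
  roi1 <- list(name = "tiny", x = 30, y = 30, z = 30, radius = 2.9)
  expect_equal(sum(sphere_mask(roi1, aff, c(21, 21, 21))), 1)

  # translating the center by one voxel spacing translates the mask
  roi_sh <- list(name = "shift", x = 33, y = 30, z = 30, radius = 6)
  mask_sh <- sphere_mask(roi_sh, aff, c(21, 21, 21))
  expect_equal(mask_sh[2:21, , ], mask[1:20, , ])

  # voxel count is non-decreasing in radius
  counts <- vapply(c(3, 4.5, 6, 7.5, 9), function(r) {
    sum(sphere_mask(list(name = "r", x = 30, y = 30, z = 30, radius = r),
                    aff, c(21, 21, 21)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))

  expect_error(
    sphere_mask(list(name = "far", x = 500, y = 0, z = 0, radius = 6),
                aff, c(21, 21, 21)),
    "far.*outside the grid"
  )
})

test_that("ROI extraction averages sphere voxels and respects list order", {
  aff <- diag(c(3, 3, 3, 1))
  dims <- c(21, 21, 21); n_vol <- 40
  rois <- tibble::tibble(
    name = c("A", "B"),
    x = c(15, 45), y = c(30, 30), z = c(30, 30), radius = 6
  )
  vol <- array(0, dim = c(dims, n_vol))

  # constant-valued volume -> constant series
  vol[] <- 7.5
  s <- extract_roi_series(vol, rois, tr_s = 2, affine = aff)
  expect_true(all(abs(lfogcnet:::ts_matrix(s) - 7.5) < 1e-12))

  # paint each sphere with its own known signal, zeros elsewhere
  sin_a <- sin(2 * pi * 0.07 * 2 * seq_len(n_vol))
  mask_a <- sphere_mask(rois[1, ], aff, dims)
  mask_b <- sphere_mask(rois[2, ], aff, dims)
  vol[] <- 0
  for (t in seq_len(n_vol)) {
    frame <- array(0, dims)
    frame[mask_a] <- sin_a[t]
    frame[mask_b] <- 3
    vol[, , , t] <- frame
  }
  s2 <- extract_roi_series(vol, rois, tr_s = 2, affine = aff)
  expect_equal(s2$A, sin_a, tolerance = 1e-12)
  expect_equal(s2$B, rep(3, n_vol), tolerance = 1e-12)

  # column order follows the ROI list, independent of spatial position
  s3 <- extract_roi_series(vol, rois[2:1, ], tr_s = 2, affine = aff)
  expect_equal(names(s3), c("B", "A"))
  expect_equal(s3$A, s2$A)

  # NaN voxels inside a mask are an error naming the count
  vol[which(mask_a)[1] + prod(dims) * 2] <- NaN
  expect_error(extract_roi_series(vol, rois, tr_s = 2, affine = aff),
               "non-finite voxel")
})

test_that("ROI extraction reads NIfTI volumes with their affine and TR", {
  dims <- c(21, 21, 21); n_vol <- 12
  vol <- array(rnorm(prod(dims) * n_vol, mean = 5), dim = c(dims, n_vol))
  img <- RNifti::asNifti(vol, reference = NULL)
  img <- RNifti::`pixdim<-`(img, c(3, 3, 3, 2))
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, path)
  roi <- tibble::tibble(name = "mid", x = 30, y = 30, z = 30, radius = 6)
  s <- extract_roi_series(path, roi, tr_s = 2)
  expect_equal(nrow(s), n_vol)
  expect_equal(attr(s, "tr_s"), 2)
})

test_that("detrending removes a ramp and the band-pass shapes the spectrum", {
  tr <- 2; n <- 300
  ramp <- roi_ts(data.frame(r = seq(0, 100, length.out = n)), tr_s = tr)
  out <- detrend_bandpass(ramp)
  expect_lt(max(abs(out$r)), 1e-6 * 100)

  t_s <- seq_len(n) * tr
  inband <- roi_ts(data.frame(x = sin(2 * pi * 0.07 * t_s)), tr_s = tr)
  keep <- 50:(n - 50)  # away from edges
  amp <- max(abs(detrend_bandpass(inband)$x[keep]))
  expect_gt(amp, 0.95); expect_lt(amp, 1.05)

  # 0.01 Hz tone attenuated by >= 90% in RMS, consistent with the
  # filter's squared frequency response (independent freqz oracle)
  slow <- roi_ts(data.frame(x = sin(2 * pi * 0.01 * t_s)), tr_s = tr)
  flt <- detrend_bandpass(slow)$x
  rms_ratio <- sqrt(mean(flt[keep]^2)) / sqrt(mean(slow$x[keep]^2))
  expect_lt(rms_ratio, 0.10)
  bf <- signal::butter(4, c(0.04, 0.1) / 0.25, type = "pass")
  z <- exp(-1i * 2 * pi * 0.01 * tr * (seq_along(bf$b) - 1))
  h01 <- sum(bf$b * z) / sum(bf$a * z)  # direct response at 0.01 Hz
  expect_lt(rms_ratio, 5 * Mod(h01)^2 + 1e-4)  # forward-backward = |H|^2

  expect_error(detrend_bandpass(inband, f_lo = 0.04, f_hi = 0.3),
               "Nyquist")
})

test_that("filtering is idempotent and concentrates spectral mass in band", {
  # idempotence on the data class the pipeline actually filters:
  # band-limited subject series
  subj <- simulate_var(motor_network_spec(), 237, seed = 31,
                       band_limited = TRUE)
  once <- detrend_bandpass(subj)
  twice <- detrend_bandpass(once)
  for (col in names(once)) {
    r1 <- sqrt(mean(once[[col]]^2)); r2 <- sqrt(mean(twice[[col]]^2))
    expect_lt(abs(r2 - r1) / r1, 0.02)
  }
  expect_true(attr(once, "filtered"))

  # >= 90% of post-filter spectral mass lies in the band even for
  # white-noise input (periodogram oracle, one-bin slack)
  set.seed(31)
  noise <- roi_ts(data.frame(a = rnorm(400), b = rnorm(400)), tr_s = 2)
  fnoise <- detrend_bandpass(noise)
  for (col in c("a", "b")) {
    pg <- periodogram(fnoise[[col]], tr = 2)
    df <- pg$freq[1]
    inband <- pg$freq >= 0.04 - df & pg$freq <= 0.1 + df
    expect_gte(sum(pg$power[inband]) / sum(pg$power), 0.90)
  }
})
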