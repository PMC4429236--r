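test_that("the Hilbert envelope recovers tone amplitudes", {
  fs <- 12000
  tt <- seq_len(fs * 30) / fs
  tone <- audio_track(0.5 * sin(2 * pi * 440 * tt), fs)
  env <- extract_envelope(tone)
  interior <- env$values[3:(length(env$values) - 2)]
  expect_true(all(abs(interior - 0.5) / 0.5 < 0.02))
  # silence
  silent <- audio_track(rep(0, fs * 12), fs)
  expect_lt(max(extract_envelope(silent)$values), 1e-9)
  # infeasible band
  low <- audio_track(rnorm(8000 * 6), 8000)
  expect_error(extract_envelope(low, band = c(4, 4000)), "resolve")
})

test_that("a slow amplitude modulator survives envelope downsampling", {
  fs <- 12000
  n <- fs * 60
  mod <- 0.5 * (1 + 0.8 * sin(2 * pi * 0.2 * seq_len(n) / fs))
  am <- audio_track(0.4 * mod * sin(2 * pi * 440 * seq_len(n) / fs), fs)
  env <- extract_envelope(am)
  mod_tr <- mod[seq(1, n, by = fs * 1.5)]
  expect_gt(cor(env$values, mod_tr), 0.95)
})

test_that("envelope alignment pads, convolves, and crops", {
  env <- structure(list(values = c(1, rep(0, 19)), tr = 1.5,
                        band = c(4, 4000), source_rate = 12000),
                   class = "envelope")
  v <- align_envelope_to_run(env, lead_in_trs = 2, crop_trs = 0,
                             hrf = FALSE)
  expect_equal(v, c(0, 0, 1, rep(0, 19)))
  v2 <- align_envelope_to_run(env, lead_in_trs = 2, crop_trs = 3,
                              hrf = FALSE)
  expect_equal(length(v2), 19)
  # with HRF: peak delayed ~5 s from the event
  vh <- align_envelope_to_run(env, lead_in_trs = 2, crop_trs = 0)
  expect_equal(which.max(vh), 2 + 1 + round(5 / 1.5), tolerance = 1)
})

test_that("envelope-correlated voxels define the early auditory ROI", {
  set.seed(51)
  T_len <- 157; V <- 60; N <- 5
  env <- convolve_hrf(abs(rnorm(T_len)), hrf_double_gamma(1.5))
  arr <- array(rnorm(T_len * V * N), c(T_len, V, N))
  for (s in seq_len(N)) arr[, 23, s] <- env + 0.2 * rnorm(T_len)
  roi <- define_a1(arr, env, k = 4)
  expect_equal(roi$voxels[1], 23)
  expect_gt(roi$correlations[1], 0.9)
  # k equal to the voxel count returns the whole grid
  expect_setequal(define_a1(arr, env, k = V)$voxels, seq_len(V))
  # correlations invariant to positive voxel-wise scaling
  arr2 <- arr
  arr2[, 23, ] <- arr2[, 23, ] * 7
  expect_equal(define_a1(arr2, env, k = 4)$all_correlations[23],
               roi$all_correlations[23], tolerance = 1e-12)
  expect_error(define_a1(arr, env[-1], k = 4), "does not match")
  expect_error(define_a1(arr, env, k = V + 1), "exceeds")
})

test_that("axis ROIs partition the mask along the projection", {
  mask <- array(FALSE, c(12, 5, 5))
  mask[, 2:3, 3] <- TRUE
  ax <- define_axis_rois(mask, start = c(1, 2, 3), end = c(12, 2, 3),
                         n_rois = 4)
  sizes <- lengths(ax$rois)
  expect_equal(sum(sizes), sum(mask))
  expect_lte(diff(range(sizes)), 2)
  expect_false(any(duplicated(unlist(ax$rois))))
  expect_true(all(unlist(ax$rois) %in% which(mask)))
  expect_true(all(diff(ax$centroids) > 0))
  expect_error(define_axis_rois(mask, c(1, 1, 1), c(1, 1, 1), 3),
               "differ")
  expect_error(define_axis_rois(array(FALSE, c(3, 3, 3)),
                                c(1, 1, 1), c(3, 3, 3), 2), "empty")
})

test_that("ROI profiles reduce to voxel ISC and flag condition gaps", {
  set.seed(52)
  T_len <- 80; V <- 9; N <- 6
  shared <- rnorm(T_len)
  long_trw <- array(rnorm(T_len * V * N), c(T_len, V, N))
  meas <- long_trw
  for (s in seq_len(N)) {
    long_trw[, 1:4, s] <- shared + 0.8 * rnorm(T_len) # intact: shared
  }
  arrs <- list(measure = meas, intact = long_trw)
  prof <- roi_profile(arrs, 1:4)
  expect_equal(prof$condition, c("measure", "intact"))
  expect_gt(prof$mean_R[2], prof$mean_R[1])
  expect_lt(prof$p_vs_intact[1], 0.05)
  expect_true(is.na(prof$t_vs_intact[2]))
  # identical subjects: ISC 1, SE 0
  same <- array(rep(rnorm(T_len * V), N), c(T_len, V, N))
  p1 <- roi_profile(list(intact = same), 1:5)
  expect_equal(p1$mean_R, 1)
  expect_equal(p1$se, 0)
  # a one-voxel ROI equals loo_isc at that voxel
  pv <- roi_profile(list(intact = long_trw), 3)
  expect_equal(pv$mean_R, loo_isc(long_trw[, 3, ])$R, tolerance = 1e-12)
  # single subject: leave-one-out undefined
  solo <- array(rnorm(T_len * V), c(T_len, V, 1))
  expect_error(roi_profile(list(intact = solo), 1:3), "2 subjects")
  expect_error(roi_profile(arrs, integer(0)), "empty ROI")
})
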