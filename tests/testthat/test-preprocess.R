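make_run <- function(series_list, tr = 1.5) {
  T_len <- length(series_list[[1]])
  V <- length(series_list)
  d <- c(V, 1, 1, T_len)
  arr <- array(0, d)
  for (v in seq_len(V)) arr[v, 1, 1, ] <- series_list[[v]]
  bold_run(arr, tr)
}

test_that("detrending removes linear and constant components", {
  T_len <- 157
  run <- make_run(list(5 + 0.3 * seq_len(T_len), rep(2, T_len)))
  out <- detrend_highpass(run)
  rng <- 0.3 * T_len
  expect_lt(max(abs(out$data[1, 1, 1, ])) / rng, 1e-8)
  expect_lt(max(abs(out$data[2, 1, 1, ])), 1e-8)
  expect_lt(abs(mean(out$data[1, 1, 1, ])), 1e-8)
})

test_that("high-pass response passes 0.05 Hz and rejects 0.002 Hz", {
  T_len <- 157; tr <- 1.5
  t <- seq_len(T_len) * tr
  gain <- function(f) {
    run <- make_run(list(sin(2 * pi * f * t)), tr)
    y <- detrend_highpass(run)$data[1, 1, 1, ]
    sqrt(sum(y^2) / sum(sin(2 * pi * f * t)^2))
  }
  expect_gt(gain(0.05), 0.9)
  expect_lt(gain(0.002), 0.1)
})

test_that("too-short series are rejected", {
  run <- make_run(list(rnorm(20)))
  expect_error(detrend_highpass(run), "too short")
})

test_that("spatial smoothing matches the FWHM definition", {
  d <- c(12, 12, 12)
  a <- array(0, c(d, 2)); a[6, 6, 6, ] <- 1
  run <- bold_run(a, 1.5, voxel_size = c(3, 3, 3))
  sm <- smooth_spatial(run, fwhm_mm = 6)
  # response 3 mm (= fwhm/2) from the center is half the peak
  ratio <- sm$data[7, 6, 6, 1] / sm$data[6, 6, 6, 1]
  expect_lt(abs(ratio - 0.5), 0.01)
  # interior impulse: volume sum preserved
  expect_lt(abs(sum(sm$data[, , , 1]) - 1), 1e-3)
  # constant volume unchanged
  const <- bold_run(array(3, c(4, 4, 4, 2)), 1.5)
  smc <- smooth_spatial(const, 6)
  expect_lt(max(abs(smc$data - 3)), 1e-9)
  expect_error(smooth_spatial(const, -1), "non-negative")
})

test_that("smoothing commutes with constant offsets", {
  set.seed(8)
  a <- array(rnorm(6^3 * 2), c(6, 6, 6, 2))
  r1 <- smooth_spatial(bold_run(a, 1.5), 6)
  r2 <- smooth_spatial(bold_run(a + 10, 1.5), 6)
  expect_equal(r2$data, r1$data + 10, tolerance = 1e-10)
})

test_that("initial-volume cropping follows the run timing", {
  run <- make_run(list(rnorm(172)))
  out <- crop_initial(run, 15)
  expect_equal(dim(out$data)[4], 157)
  expect_identical(out$data[1, 1, 1, ], run$data[1, 1, 1, 16:172])
  expect_identical(crop_initial(run, 0), run)
  expect_error(crop_initial(run, 172), "cannot crop")
})

test_that("the pipeline composes the stages in order", {
  set.seed(4)
  a <- array(rnorm(4^3 * 60), c(4, 4, 4, 60))
  run <- bold_run(a, 1.5)
  piped <- preprocess_run(run, list(cutoff_hz = 0.01, fwhm_mm = 6,
                                    crop_trs = 10))
  manual <- crop_initial(smooth_spatial(detrend_highpass(run, 0.01), 6), 10)
  expect_equal(piped$data, manual$data, tolerance = 1e-12)
  expect_equal(piped$provenance, manual$provenance)
  # all stages disabled: identity
  ident <- preprocess_run(run, list(cutoff_hz = NULL, fwhm_mm = 0,
                                    crop_trs = 0))
  expect_identical(ident$data, run$data)
})

test_that("filtering is stable under repetition away from the cutoff", {
  # passband components are nearly unchanged by a second pass; edge
  # samples carry the zero-phase filter's unavoidable boundary transient,
  # so stability is asserted over the interior
  T_len <- 157; tr <- 1.5
  t <- seq_len(T_len) * tr
  run <- make_run(list(sin(2 * pi * 0.05 * t) + 0.5 * sin(2 * pi * 0.2 * t)),
                  tr)
  once <- detrend_highpass(run)
  twice <- detrend_highpass(once)
  interior <- 31:(T_len - 30)
  rel <- max(abs(twice$data[1, 1, 1, interior] -
                   once$data[1, 1, 1, interior])) /
    max(abs(once$data))
  expect_lt(rel, 0.03)
  # signals the filter removes entirely are true fixed points
  flat <- detrend_highpass(make_run(list(3 + 0.1 * seq_len(T_len)), tr))
  again <- detrend_highpass(flat)
  expect_lt(max(abs(again$data - flat$data)), 1e-8)
})
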