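test_that("identical subjects give perfect leave-one-out correlation", {
  x <- matrix(rep(sin(1:30), 4), 30, 4)
  res <- loo_isc(x)
  expect_equal(res$r, rep(1, 4))
  expect_equal(res$R, 1)
})

test_that("loo_isc matches a direct formula oracle on a small fixture", {
  # r_j = corr(x_j, mean of others), Pearson computed from raw sums
  pearson <- function(a, b) {
    n <- length(a)
    num <- sum(a * b) - sum(a) * sum(b) / n
    den <- sqrt((sum(a^2) - sum(a)^2 / n) * (sum(b^2) - sum(b)^2 / n))
    num / den
  }
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8); c_ <- c(4, 3, 2, 1)
  expect_warning(res <- loo_isc(cbind(a, b, c_)), "zero-variance")
  expect_equal(res$r[1], pearson(a, (b + c_) / 2))
  expect_equal(res$r[3], pearson(c_, (a + b) / 2))
  # subject b faces the constant mean of a and c: undefined, excluded
  expect_true(is.na(res$r[2]))
  expect_equal(res$n_used, 2)
  expect_equal(res$R, mean(res$r[c(1, 3)]))
})

test_that("loo_isc is invariant to affine transforms that preserve the group mean", {
  set.seed(11)
  x <- matrix(rnorm(50 * 5), 50, 5)
  # common positive scale and arbitrary per-subject offsets leave every
  # r_j unchanged (offsets cancel in the correlation; the common scale
  # rescales subject and leave-one-out mean alike)
  y <- sweep(2.7 * x, 2, rnorm(5), "+")
  expect_equal(loo_isc(y)$r, loo_isc(x)$r, tolerance = 1e-12)
  # rescaling one subject changes only the leave-one-out averages it
  # enters: its own r_j is unchanged
  z <- x
  z[, 3] <- 5 * z[, 3]
  expect_equal(loo_isc(z)$r[3], loo_isc(x)$r[3], tolerance = 1e-12)
})

test_that("vectorized loo_isc agrees with the per-voxel version", {
  set.seed(12)
  arr <- array(rnorm(40 * 7 * 5), c(40, 7, 5))
  all <- loo_isc_all(arr)
  for (v in c(1, 4, 7)) {
    one <- loo_isc(arr[, v, ])
    expect_equal(all$r[, v], one$r, tolerance = 1e-12)
    expect_equal(all$R[v], one$R, tolerance = 1e-12)
  }
})

test_that("phase randomization preserves the spectrum and variance", {
  set.seed(13)
  for (T_len in c(157, 156)) { # odd and even lengths
    x <- rnorm(T_len)
    s <- phase_randomize(x, seed = 3)
    expect_lt(max(abs(Mod(fft(s)) - Mod(fft(x)))) / max(Mod(fft(x))), 1e-9)
    v0 <- mean((x - mean(x))^2)
    expect_lt(abs(mean((s - mean(s))^2) - v0) / v0, 1e-6)
    # circular autocovariance preserved exactly (it is the inverse
    # transform of the power spectrum)
    circ_acov <- function(v) {
      vc <- v - mean(v)
      Re(fft(Mod(fft(vc))^2, inverse = TRUE)) / length(v)^2
    }
    expect_equal(circ_acov(s), circ_acov(x), tolerance = 1e-9)
    expect_identical(phase_randomize(x, seed = 3), s)
  }
  # constant series: only DC energy, surrogate unchanged
  cst <- rep(2.5, 16)
  expect_equal(phase_randomize(cst, seed = 1), cst, tolerance = 1e-12)
  expect_error(phase_randomize(c(1, 2, 3), seed = 1), "length >= 4")
})

test_that("mutually phase-randomized subjects decorrelate", {
  set.seed(14)
  base <- as.numeric(stats::filter(rnorm(400), rep(1 / 5, 5),
                                   circular = TRUE))
  subj <- sapply(1:10, function(j) phase_randomize(base, seed = 100 + j))
  expect_lt(abs(loo_isc(subj)$R), 0.05)
})

test_that("the null distribution is seeded, centered, and matches a brute-force surrogate loop", {
  set.seed(15)
  x <- matrix(rnorm(157 * 8), 157, 8)
  n1 <- isc_null_distribution(x, n_perm = 400, seed = 9)
  expect_identical(isc_null_distribution(x, n_perm = 400, seed = 9), n1)
  expect_lt(abs(mean(n1)), 3 * sd(n1) / sqrt(length(n1)))
  # independent route: R-level phase_randomize + loo_isc
  brute <- vapply(1:400, function(k) {
    xs <- sapply(seq_len(ncol(x)), function(j) {
      phase_randomize(x[, j], seed = 7000 + 13 * k + j)
    })
    loo_isc(xs)$R
  }, numeric(1))
  expect_lt(abs(mean(brute)), 3 * sd(brute) / sqrt(length(brute)))
  expect_lt(abs(sd(n1) - sd(brute)) / sd(brute), 0.25)
})

test_that("empirical p-values are approximately uniform under the null", {
  set.seed(16)
  arr <- array(rnorm(100 * 200 * 6), c(100, 200, 6))
  obs <- loo_isc_all(arr)
  null <- isc_null_distribution(arr, n_perm = 500, seed = 4)
  p <- isc_pvalue(obs$R, null)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation p-values follow the add-one estimator", {
  null <- (-49:49) / 100
  expect_equal(isc_pvalue(0.9, null), 1 / 100)
  expect_equal(isc_pvalue(0, null), (1 + 50) / 100)
  expect_equal(isc_pvalue(-0.9, null), 1)
  # monotone non-increasing in the observed value
  ps <- vapply(seq(-0.6, 0.6, by = 0.05), isc_pvalue, numeric(1),
               null_samples = null)
  expect_true(all(diff(ps) <= 0))
})

test_that("isc_map composes observation, null, p-values, and FDR", {
  set.seed(17)
  T_len <- 60; V <- 30; N <- 5
  shared <- matrix(rnorm(T_len * 10), T_len, 10)
  arr <- array(rnorm(T_len * V * N), c(T_len, V, N))
  for (s in seq_len(N)) {
    arr[, 1:10, s] <- shared + 0.3 * matrix(rnorm(T_len * 10), T_len, 10)
  }
  res <- isc_map(arr, n_perm = 200, seed = 5)
  expect_s3_class(res, "isc_result")
  expect_equal(length(res$R), V)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$mask[1:10]))
  expect_lt(mean(res$mask[11:V]), 0.3)
  # mask implies p below the selected threshold
  expect_true(all(res$p[res$mask] <= res$fdr$p_threshold))
})
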