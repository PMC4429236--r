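#' Leave-one-out inter-subject correlation at one voxel
#'
#' For each subject `j`, computes the Pearson correlation `r_j` between
#' that subject's time course and the average time course of the remaining
#' subjects, and returns the simple average `R = mean(r_j)` (no Fisher
#' transform, unless `fisher_z = TRUE`, in which case r values are averaged
#' in z space and transformed back). Subjects whose own series, or whose
#' leave-one-out average, has zero variance get `r_j = NA` and are excluded
#' from `R` with a warning.
#'
#' @param x T x N matrix (time points by subjects) or list of equal-length
#'   numeric vectors.
#' @param fisher_z average in Fisher z space (default `FALSE`).
#' @return list with `r` (length-N vector, may contain `NA`), `R` (mean),
#'   and `n_used` (subjects entering the mean).
#' @export
loo_isc <- function(x, fisher_z = FALSE) {
  if (is.list(x)) x <- do.call(cbind, x)
  stopifnot(is.matrix(x))
  N <- ncol(x)
  if (N < 2) stop("leave-one-out ISC needs at least 2 subjects")
  if (nrow(x) < 3) stop("time courses must have length >= 3")
  tot <- rowSums(x)
  r <- vapply(seq_len(N), function(j) {
    xj <- x[, j]
    oth <- (tot - xj) / (N - 1)
    if (sd(xj) == 0 || sd(oth) == 0) NA_real_ else cor(xj, oth)
  }, numeric(1))
  n_used <- sum(!is.na(r))
  if (n_used < N) {
    warning(N - n_used,
            " subject(s) with zero-variance series excluded from R")
  }
  R <- if (n_used == 0) NA_real_ else if (fisher_z) {
    tanh(mean(atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)), na.rm = TRUE))
  } else {
    mean(r, na.rm = TRUE)
  }
  list(r = r, R = R, n_used = n_used)
}

#' Leave-one-out ISC for every voxel of a cohort array
#'
#' Vectorized version of [loo_isc()] over a `T x V x N` array.
#'
#' @param arr array `(time, voxel, subject)`.
#' @return list with `r` (N x V matrix) and `R` (length-V vector).
#' @export
loo_isc_all <- function(arr) {
  stopifnot(length(dim(arr)) == 3)
  T_len <- dim(arr)[1]; V <- dim(arr)[2]; N <- dim(arr)[3]
  if (N < 2) stop("leave-one-out ISC needs at least 2 subjects")
  tot <- apply(arr, c(1, 2), sum) # T x V
  r <- matrix(NA_real_, N, V)
  for (j in seq_len(N)) {
    xj <- arr[, , j]
    oth <- (tot - xj) / (N - 1)
    xj <- sweep(xj, 2, colMeans(xj))
    oth <- sweep(oth, 2, colMeans(oth))
    num <- colSums(xj * oth)
    den <- sqrt(colSums(xj^2) * colSums(oth^2))
    ok <- den > 0
    r[j, ok] <- num[ok] / den[ok]
  }
  list(r = r, R = colMeans(r, na.rm = TRUE))
}

#' Phase-randomized surrogate of a time series
#'
#' Applies an FFT, rotates each positive-frequency component by an
#' independent uniform random phase (mirrored conjugate-symmetrically so
#' the output is real), and inverts the transform. The DC component is
#' untouched; for even-length series the Nyquist component keeps a random
#' sign. The magnitude spectrum — hence variance and autocorrelation — is
#' preserved exactly.
#'
#' @param x numeric series of length >= 4.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return surrogate series of the same length.
#' @export
phase_randomize <- function(x, seed = NULL) {
  drop(phase_surrogates(x, 1L, seed))
}

#' Ensemble of phase-randomized surrogates
#'
#' Vectorized generation of `n` independent surrogates of one series (see
#' [phase_randomize()]).
#'
#' @param x numeric series of length >= 4.
#' @param n number of surrogates.
#' @param seed optional integer seed.
#' @return `length(x)` x `n` matrix, one surrogate per column.
#' @export
phase_surrogates <- function(x, n, seed = NULL) {
  T_len <- length(x)
  if (T_len < 4) stop("series must have length >= 4")
  if (!is.null(seed)) set.seed(as.integer(seed))
  X <- fft(x)
  h <- (T_len - 1) %/% 2
  F <- matrix(X, T_len, n)
  ph <- matrix(runif(h * n, 0, 2 * pi), h, n)
  rot <- exp(1i * ph)
  F[2:(h + 1), ] <- F[2:(h + 1), ] * rot
  F[T_len:(T_len - h + 1), ] <- Conj(F[2:(h + 1), , drop = FALSE])
  if (T_len %% 2 == 0) {
    ny <- T_len / 2 + 1
    F[ny, ] <- F[ny, ] * sample(c(-1, 1), n, replace = TRUE)
  }
  Re(mvfft(F, inverse = TRUE)) / T_len
}

#' Null distribution of leave-one-out ISC by phase randomization
#'
#' For each replicate, every subject's series at every voxel is
#' independently phase-randomized (spectrum preserved) and `R` is
#' recomputed, yielding a per-voxel null sample of size `n_perm`. The
#' computation runs in a compiled kernel with its own seeded RNG stream, so
#' results are bit-reproducible given `seed` and independent of R's RNG
#' state.
#'
#' @param x `T x N` matrix (one voxel) or `T x V x N` array.
#' @param n_perm number of replicates (default 5000; >= 100 recommended).
#' @param seed integer seed.
#' @return numeric vector of length `n_perm` (matrix input) or `V x n_perm`
#'   matrix (array input) of null `R` values.
#' @export
isc_null_distribution <- function(x, n_perm = 5000, seed = 1) {
  if (is.matrix(x)) {
    arr <- array(x, c(nrow(x), 1L, ncol(x)))
    return(drop(isc_null_kernel(arr, as.integer(n_perm), as.numeric(seed))))
  }
  stopifnot(length(dim(x)) == 3)
  isc_null_kernel(x, as.integer(n_perm), as.numeric(seed))
}

#' Permutation p-value for observed ISC
#'
#' One-sided upper-tail p-value with the add-one estimator:
#' `p = (1 + #\{null >= R_obs\}) / (1 + n_perm)`, so `p > 0` always.
#'
#' @param R_obs observed `R` (scalar or length-V vector).
#' @param null_samples numeric vector (one voxel) or `V x n_perm` matrix of
#'   null `R` values.
#' @return p-value(s) in `(0, 1]`.
#' @export
isc_pvalue <- function(R_obs, null_samples) {
  if (is.matrix(null_samples)) {
    stopifnot(length(R_obs) == nrow(null_samples))
    n_perm <- ncol(null_samples)
    exceed <- rowSums(null_samples >= R_obs, na.rm = TRUE)
  } else {
    if (!length(null_samples)) stop("empty null sample")
    stopifnot(length(R_obs) == 1)
    n_perm <- length(null_samples)
    exceed <- sum(null_samples >= R_obs, na.rm = TRUE)
  }
  (1 + exceed) / (1 + n_perm)
}

#' Voxelwise ISC map with significance
#'
#' Convenience wrapper running [loo_isc_all()], [isc_null_distribution()],
#' [isc_pvalue()], and [fdr_threshold()] on one condition's cohort array.
#'
#' @param arr `T x V x N` array for one condition.
#' @param n_perm permutation count (default 5000).
#' @param seed integer seed for the null.
#' @param q_star FDR level (default 0.05).
#' @param by_correction use the dependence-corrected FDR rule.
#' @param keep_null retain the full null sample matrix (default `FALSE`).
#' @return object of class `isc_result`: list with `R`, `r`, `p`, `mask`,
#'   `fdr` (the [fdr_threshold()] decision), `n_perm`, and optionally
#'   `null`.
#' @export
isc_map <- function(arr, n_perm = 5000, seed = 1, q_star = 0.05,
                    by_correction = FALSE, keep_null = FALSE) {
  obs <- loo_isc_all(arr)
  null <- isc_null_distribution(arr, n_perm = n_perm, seed = seed)
  if (!is.matrix(null)) null <- matrix(null, nrow = 1)
  p <- isc_pvalue(obs$R, null)
  fdr <- fdr_threshold(p, q_star = q_star, by_correction = by_correction)
  out <- list(R = obs$R, r = obs$r, p = p, mask = fdr$mask, fdr = fdr,
              n_perm = n_perm)
  if (keep_null) out$null <- null
  structure(out, class = "isc_result")
}

#' @export
print.isc_result <- function(x, ...) {
  cat(sprintf(
    "isc_result: %d voxels, %d permutations; %d significant (q* = %g)\n",
    length(x$R), x$n_perm, sum(x$mask), x$fdr$q_star))
  invisible(x)
}
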