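#' Audio envelope at the BOLD sampling rate
#'
#' Band-pass filters the waveform (zero-phase Butterworth: second-order
#' high-pass at the lower edge cascaded with a fourth-order low-pass at the
#' upper edge), takes the magnitude of the analytic signal (Hilbert
#' envelope), and decimates to `1/tr` Hz through a cascade of FIR
#' anti-aliasing low-pass stages.
#'
#' @param track an [audio_track()] whose sample rate exceeds twice the
#'   upper band edge.
#' @param band lower/upper band edges in Hz (default `c(4, 4000)`).
#' @param tr target sampling interval in seconds (default 1.5);
#'   `sample_rate * tr` must be an integer decimation factor.
#' @return object of class `envelope`: list with `values` (non-negative,
#'   one per TR), `tr`, `band`, `source_rate`.
#' @export
extract_envelope <- function(track, band = c(4, 4000), tr = 1.5) {
  stopifnot(inherits(track, "audio_track"), length(band) == 2,
            band[1] > 0, band[2] > band[1])
  fs <- track$sample_rate
  if (fs <= 2 * band[2]) {
    stop("sample rate ", fs, " Hz cannot resolve a band up to ", band[2],
         " Hz")
  }
  x <- track$samples
  W1 <- band[1] / (fs / 2); W2 <- band[2] / (fs / 2)
  hp <- signal::butter(2, W1, type = "high")
  lp <- signal::butter(4, W2, type = "low")
  x <- drop(filtfilt_cols(as.numeric(hp$b), as.numeric(hp$a),
                          matrix(x, ncol = 1),
                          pad = as.integer(ceiling(6 / W1))))
  x <- drop(filtfilt_cols(as.numeric(lp$b), as.numeric(lp$a),
                          matrix(x, ncol = 1),
                          pad = as.integer(ceiling(6 / W2))))
  # analytic signal magnitude
  n <- length(x)
  X <- fft(x)
  hmask <- numeric(n)
  if (n %% 2 == 0) {
    hmask[c(1, n / 2 + 1)] <- 1
    hmask[2:(n / 2)] <- 2
  } else {
    hmask[1] <- 1
    hmask[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(fft(X * hmask, inverse = TRUE) / n)
  # FIR anti-aliased decimation cascade down to 1/tr Hz
  q_total <- fs * tr
  if (abs(q_total - round(q_total)) > 1e-8) {
    stop("sample_rate * tr must be an integer decimation factor")
  }
  q_total <- as.integer(round(q_total))
  for (q in decimation_stages(q_total)) {
    env <- decimate_fir(env, q)
  }
  structure(list(values = pmax(env, 0), tr = tr, band = band,
                 source_rate = fs),
            class = "envelope")
}

# zero-phase FIR decimation: 30th-order lowpass at 1/q Nyquist applied as a
# centered convolution with edge-replicate padding, then every q-th sample
decimate_fir <- function(x, q) {
  b <- as.numeric(signal::fir1(30, 1 / q))
  b <- b / sum(b) # enforce unit DC gain
  r <- (length(b) - 1L) %/% 2L
  n <- length(x)
  padded <- c(rep(x[1], r), x, rep(x[n], r))
  y <- stats::filter(padded, b, sides = 2)
  y <- as.numeric(y)[(r + 1L):(r + n)]
  y[seq(1L, n, by = q)]
}

# factor an integer decimation ratio into stages <= 13 (FIR-friendly)
decimation_stages <- function(q) {
  stages <- integer(0)
  while (q > 1) {
    f <- max(which(q %% seq_len(min(q, 13L)) == 0))
    if (f == 1L) stop("cannot factor decimation ratio ", q,
                      " into stages <= 13")
    stages <- c(stages, f)
    q <- q %/% f
  }
  sort(stages, decreasing = TRUE)
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("envelope: %d samples at 1/%g Hz (band %g-%g Hz)\n",
              length(x$values), x$tr, x$band[1], x$band[2]))
  invisible(x)
}

#' Align a stimulus envelope to preprocessed runs
#'
#' Prepends zeros for the silent lead-in, optionally convolves with the
#' canonical HRF (lag compensation for the hemodynamic delay), and crops
#' the same initial TRs as the BOLD preprocessing.
#'
#' @param env an [extract_envelope()] result.
#' @param lead_in_trs silent TRs preceding the stimulus (default 2,
#'   i.e. 3 s at TR 1.5 s).
#' @param crop_trs initial TRs cropped from the runs (default 15).
#' @param hrf convolve with [hrf_double_gamma()] (default `TRUE`).
#' @return numeric vector aligned with cropped run time courses.
#' @export
align_envelope_to_run <- function(env, lead_in_trs = 2, crop_trs = 15,
                                  hrf = TRUE) {
  stopifnot(inherits(env, "envelope"))
  v <- c(rep(0, lead_in_trs), env$values)
  if (hrf) v <- convolve_hrf(v, hrf_double_gamma(env$tr))
  if (crop_trs >= length(v)) stop("crop longer than envelope")
  if (crop_trs > 0) v[-seq_len(crop_trs)] else v
}

#' Define the early-auditory ROI from envelope correlation
#'
#' Correlates the cohort-average time course of every voxel with the
#' (aligned) stimulus audio envelope and returns the `k` most correlated
#' voxels — the operational definition of early auditory cortex (A1+).
#'
#' @param arr `T x V x N` cohort array (typically the preprocessed intact
#'   condition).
#' @param env_values aligned envelope vector of length `T` (see
#'   [align_envelope_to_run()]).
#' @param k ROI size in voxels (default 50).
#' @return object of class `roi`: list with `voxels` (indices into the
#'   flattened grid), `correlations` (per-ROI-voxel), `all_correlations`.
#' @export
define_a1 <- function(arr, env_values, k = 50) {
  stopifnot(length(dim(arr)) == 3)
  if (length(env_values) != dim(arr)[1]) {
    stop("envelope length (", length(env_values),
         ") does not match run length (", dim(arr)[1], ")")
  }
  if (k > dim(arr)[2]) stop("k exceeds voxel count")
  avg <- apply(arr, c(1, 2), mean) # T x V cohort average
  cc <- suppressWarnings(cor(env_values, avg))[1, ]
  cc[is.na(cc)] <- -Inf
  ord <- order(cc, decreasing = TRUE)
  sel <- ord[seq_len(k)]
  structure(list(voxels = sel, correlations = cc[sel],
                 all_correlations = cc),
            class = "roi")
}

#' Lay out ROIs along an axis through a significance mask
#'
#' Projects every masked voxel orthogonally onto the start-to-end line,
#' cuts the projection range into `n_rois` equal-length bins, and returns
#' each bin's voxels as one ROI. ROIs are pairwise disjoint subsets of the
#' mask with centroid projections increasing along the axis; empty bins are
#' reported in the `empty` field.
#'
#' @param mask logical 3D array.
#' @param start,end axis endpoints in voxel coordinates (length 3).
#' @param n_rois number of ROIs.
#' @return object of class `roi_axis`: list with `rois` (list of voxel
#'   index vectors), `centroids` (projection of each ROI centroid),
#'   `empty` (indices of empty bins), `start`, `end`.
#' @export
define_axis_rois <- function(mask, start, end, n_rois) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3,
            length(start) == 3, length(end) == 3, n_rois >= 1)
  if (all(start == end)) stop("axis endpoints must differ")
  idx <- which(mask)
  if (!length(idx)) stop("empty mask")
  coords <- arrayInd(idx, dim(mask))
  dir <- (end - start) / sqrt(sum((end - start)^2))
  proj <- as.numeric((sweep(coords, 2, start)) %*% dir)
  rng <- range(proj)
  if (diff(rng) == 0) stop("all voxels project to one point on the axis")
  brk <- seq(rng[1], rng[2], length.out = n_rois + 1)
  bin <- pmin(findInterval(proj, brk, rightmost.closed = TRUE), n_rois)
  rois <- lapply(seq_len(n_rois), function(b) idx[bin == b])
  cent <- vapply(seq_len(n_rois), function(b) {
    if (any(bin == b)) mean(proj[bin == b]) else NA_real_
  }, numeric(1))
  structure(list(rois = rois, centroids = cent,
                 empty = which(lengths(rois) == 0),
                 start = start, end = end),
            class = "roi_axis")
}

#' @export
print.roi_axis <- function(x, ...) {
  cat("roi_axis:", length(x$rois), "ROIs, sizes",
      paste(lengths(x$rois), collapse = " "), "\n")
  invisible(x)
}

#' Per-condition reliability profile of an ROI
#'
#' For each condition, averages the time course over the ROI voxels within
#' each subject, computes leave-one-out ISC on the ROI-mean courses, and
#' reports the mean `R`, the standard error `sd(r_j)/sqrt(N)`, and the
#' per-subject `r_j`. Each scrambled condition is annotated with a paired
#' one-tailed t-test of intact-greater-than-scrambled on the per-subject
#' correlations.
#'
#' @param arrs named list of `T x V x N` arrays, one per condition.
#' @param roi voxel index vector (or an object with a `voxels` field).
#' @param intact name of the reference condition (default `"intact"`).
#' @return data.frame with columns `condition`, `mean_R`, `se`, `n`,
#'   `t_vs_intact`, `p_vs_intact`; per-subject correlations in attribute
#'   `r`.
#' @export
roi_profile <- function(arrs, roi, intact = "intact") {
  voxels <- if (is.list(roi) && !is.null(roi$voxels)) roi$voxels else
    if (is.list(roi)) unlist(roi) else roi
  if (!length(voxels)) stop("empty ROI")
  res <- lapply(arrs, function(arr) {
    stopifnot(length(dim(arr)) == 3)
    if (dim(arr)[3] < 2) stop("leave-one-out ISC needs >= 2 subjects")
    tc <- apply(arr[, voxels, , drop = FALSE], c(1, 3), mean) # T x N
    loo_isc(tc)
  })
  rmat <- vapply(res, function(z) z$r, numeric(dim(arrs[[1]])[3]))
  n <- nrow(rmat)
  prof <- data.frame(
    condition = names(arrs),
    mean_R = vapply(res, function(z) z$R, numeric(1)),
    se = apply(rmat, 2, sd) / sqrt(n),
    n = n,
    t_vs_intact = NA_real_, p_vs_intact = NA_real_,
    row.names = NULL)
  if (intact %in% names(arrs)) {
    for (i in seq_along(arrs)) {
      if (names(arrs)[i] == intact) next
      tt <- paired_ttest_onetailed(rmat[, intact], rmat[, i])
      prof$t_vs_intact[i] <- tt$t
      prof$p_vs_intact[i] <- tt$p
    }
  }
  attr(prof, "r") <- rmat
  prof
}
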