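#' BOLD run container
#'
#' A 4D voxel-by-time array with acquisition metadata. The data array has
#' dimensions `(x, y, z, t)`; `tr` is the repetition time in seconds and
#' `voxel_size` the voxel edge lengths in mm.
#'
#' @param data 4D numeric array `(x, y, z, t)`.
#' @param tr repetition time in seconds.
#' @param voxel_size numeric length-3, mm per axis (default `c(3, 3, 3)`).
#' @param subject subject identifier.
#' @param condition condition name.
#' @param provenance character vector of processing steps applied.
#' @return object of class `bold_run`.
#' @export
bold_run <- function(data, tr, voxel_size = c(3, 3, 3),
                     subject = NA, condition = NA_character_,
                     provenance = character()) {
  stopifnot(is.array(data), length(dim(data)) == 4, tr > 0,
            length(voxel_size) == 3, all(voxel_size > 0))
  if (dim(data)[4] < 2) stop("a bold_run needs at least 2 time points")
  if (any(!is.finite(data))) stop("bold_run data must be finite")
  structure(list(data = data, tr = tr, voxel_size = as.numeric(voxel_size),
                 subject = subject, condition = condition,
                 provenance = provenance),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_run: %dx%dx%d voxels x %d TRs (TR = %g s)",
              d[1], d[2], d[3], d[4], x$tr))
  if (!is.na(x$subject)) cat("  sub", x$subject)
  if (!is.na(x$condition)) cat("  cond", x$condition)
  cat("\n")
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

# run data as T x V matrix
run_matrix <- function(run) {
  d <- dim(run$data)
  t(matrix(run$data, prod(d[1:3]), d[4]))
}

# replace run data from a T x V matrix, keeping grid dims
run_from_matrix <- function(run, mat, step) {
  d <- dim(run$data)
  d[4] <- nrow(mat)
  run$data <- array(t(mat), dim = d)
  run$provenance <- c(run$provenance, step)
  run
}

#' Linear detrending and temporal high-pass filtering
#'
#' Removes the per-voxel linear trend, then applies a second-order
#' Butterworth high-pass filter forward and backward (zero phase) at the
#' given cutoff. The filtered series have approximately zero mean.
#'
#' @param run a [bold_run()].
#' @param cutoff_hz high-pass cutoff in Hz (default 0.01).
#' @return filtered [bold_run()].
#' @export
detrend_highpass <- function(run, cutoff_hz = 0.01) {
  stopifnot(inherits(run, "bold_run"), cutoff_hz > 0)
  X <- run_matrix(run)
  T_len <- nrow(X)
  if (T_len < 32) stop("series too short for filtering (need >= 32 TRs)")
  fs <- 1 / run$tr
  if (cutoff_hz >= fs / 2) stop("cutoff at or above Nyquist frequency")
  # linear detrend
  tt <- seq_len(T_len)
  D <- cbind(1, tt)
  beta <- solve(crossprod(D), crossprod(D, X))
  X <- X - D %*% beta
  # zero-phase Butterworth high-pass; reflection padding sized to the
  # filter time constant so edge transients settle
  W <- cutoff_hz / (fs / 2)
  bf <- signal::butter(2, W, type = "high")
  X <- filtfilt_cols(as.numeric(bf$b), as.numeric(bf$a), X,
                     pad = as.integer(ceiling(6 / W)))
  run_from_matrix(run, X, sprintf("detrend+highpass(%g Hz)", cutoff_hz))
}

# 1D convolution matrix with replicate (nearest-edge) padding
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(3.5 * sigma_vox))
  w <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + (-r:r), 1L), n) # clamp = replicate padding
    for (k in seq_along(j)) K[i, j[k]] <- K[i, j[k]] + w[k]
  }
  K
}

#' Spatial Gaussian smoothing
#'
#' Volume-wise separable 3D Gaussian smoothing with
#' `sigma = fwhm / (2 sqrt(2 log 2))` converted to voxel units per axis,
#' using nearest-edge padding.
#'
#' @param run a [bold_run()].
#' @param fwhm_mm kernel full width at half maximum in mm (default 6).
#' @return smoothed [bold_run()].
#' @export
smooth_spatial <- function(run, fwhm_mm = 6) {
  stopifnot(inherits(run, "bold_run"))
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (fwhm_mm == 0) return(run)
  d <- dim(run$data)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  Ks <- lapply(1:3, function(ax) {
    gauss_conv_matrix(d[ax], sigma_mm / run$voxel_size[ax])
  })
  out <- run$data
  for (t in seq_len(d[4])) {
    vol <- out[, , , t]
    m <- matrix(vol, d[1], d[2] * d[3])
    vol <- array(Ks[[1]] %*% m, d[1:3])
    vol <- aperm(vol, c(2, 1, 3))
    m <- matrix(vol, d[2], d[1] * d[3])
    vol <- aperm(array(Ks[[2]] %*% m, d[c(2, 1, 3)]), c(2, 1, 3))
    vol <- aperm(vol, c(3, 1, 2))
    m <- matrix(vol, d[3], d[1] * d[2])
    vol <- aperm(array(Ks[[3]] %*% m, d[c(3, 1, 2)]), c(2, 3, 1))
    out[, , , t] <- vol
  }
  run$data <- out
  run$provenance <- c(run$provenance, sprintf("smooth(%g mm)", fwhm_mm))
  run
}

#' Drop initial volumes
#'
#' Removes the first `n_trs` volumes of a run (hemodynamic steady-state
#' settling).
#'
#' @param run a [bold_run()].
#' @param n_trs number of initial volumes to drop (default 15).
#' @return cropped [bold_run()].
#' @export
crop_initial <- function(run, n_trs = 15) {
  stopifnot(inherits(run, "bold_run"), n_trs >= 0)
  d <- dim(run$data)
  if (n_trs >= d[4]) {
    stop("cannot crop ", n_trs, " TRs from a run of length ", d[4])
  }
  if (n_trs == 0) return(run)
  run$data <- run$data[, , , -(seq_len(n_trs)), drop = FALSE]
  run$provenance <- c(run$provenance, sprintf("crop(%d TRs)", n_trs))
  run
}

#' Full preprocessing pipeline for one run
#'
#' Applies, in fixed order: linear detrend + high-pass filter, spatial
#' smoothing, initial-volume cropping. Stages are skipped when their
#' parameter is `NULL` (filter), `0` (smoothing fwhm), or `0` (crop).
#'
#' @param run a [bold_run()].
#' @param config list with any of `cutoff_hz` (default 0.01; `NULL` skips
#'   filtering), `fwhm_mm` (default 6; 0 skips), `crop_trs` (default 15;
#'   0 skips).
#' @return preprocessed [bold_run()]; applied stages are appended to the
#'   run's `provenance`.
#' @export
preprocess_run <- function(run, config = list()) {
  defaults <- list(cutoff_hz = 0.01, fwhm_mm = 6, crop_trs = 15)
  keep_null <- "cutoff_hz" %in% names(config) &&
    is.null(config[["cutoff_hz"]])
  cfg <- utils::modifyList(defaults, config)
  if (keep_null) cfg["cutoff_hz"] <- list(NULL)
  if (!is.null(cfg$cutoff_hz)) run <- detrend_highpass(run, cfg$cutoff_hz)
  if (cfg$fwhm_mm > 0) run <- smooth_spatial(run, cfg$fwhm_mm)
  if (cfg$crop_trs > 0) run <- crop_initial(run, cfg$crop_trs)
  run
}
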