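#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with response peak at `peak` seconds,
#' undershoot peak at `undershoot` seconds, and peak-to-undershoot ratio
#' `ratio`, sampled at the TR and normalized to unit maximum.
#'
#' @param tr sampling interval in seconds.
#' @param duration_s kernel length in seconds (default 32).
#' @param peak response peak time in seconds (default 5).
#' @param undershoot undershoot peak time in seconds (default 15).
#' @param ratio peak to undershoot amplitude ratio (default 6).
#' @return numeric kernel sampled every `tr` seconds.
#' @export
hrf_double_gamma <- function(tr, duration_s = 32, peak = 5,
                             undershoot = 15, ratio = 6) {
  stopifnot(tr > 0, peak > 0, undershoot > peak, ratio > 0)
  t <- seq(0, duration_s, by = tr)
  h <- dgamma(t, shape = peak + 1, rate = 1) -
    dgamma(t, shape = undershoot + 1, rate = 1) / ratio
  h / max(h)
}

#' Convolve time courses with an HRF kernel
#'
#' Causal convolution of each column with the kernel, truncated to the
#' input length.
#'
#' @param x numeric vector or `T x V` matrix of neural time courses.
#' @param kernel HRF kernel (e.g. [hrf_double_gamma()]).
#' @return convolved series, same shape as `x`.
#' @export
convolve_hrf <- function(x, kernel) {
  vec_in <- is.null(dim(x))
  if (vec_in) x <- matrix(x, ncol = 1)
  T_len <- nrow(x)
  nk <- length(kernel)
  nfft <- stats::nextn(T_len + nk - 1, 2)
  K <- fft(c(kernel, rep(0, nfft - nk)))
  X <- mvfft(rbind(x, matrix(0, nfft - T_len, ncol(x))))
  y <- Re(mvfft(X * K, inverse = TRUE)) / nfft
  y <- y[seq_len(T_len), , drop = FALSE]
  if (vec_in) drop(y) else y
}

#' Ground-truth TRW map
#'
#' Per-voxel ground-truth temporal-receptive-window labels over a 3D grid.
#' Labels are the condition-hierarchy levels plus `"none"` (no
#' stimulus-locked signal).
#'
#' @param labels character array (3D) of labels.
#' @param voxel_size voxel edge lengths in mm (default `c(3, 3, 3)`).
#' @return object of class `truth_map`.
#' @export
truth_map <- function(labels, voxel_size = c(3, 3, 3)) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  bad <- setdiff(unique(as.vector(labels)), c(trw_hierarchy, "none"))
  if (length(bad)) stop("unknown truth labels: ", paste(bad, collapse = ", "))
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size)),
            class = "truth_map")
}

#' @export
print.truth_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("truth_map: %dx%dx%d voxels\n", d[1], d[2], d[3]))
  print(table(factor(as.vector(x$labels),
                     levels = c(trw_hierarchy, "none"))))
  invisible(x)
}

#' Default slab-layout ground truth
#'
#' Partitions the grid into six equal slabs along the x axis, labelled
#' backward, measure, phrase, section, intact, none — emulating a
#' temporo-parietal axis along which the TRW lengthens from early auditory
#' cortex toward higher-order areas.
#'
#' @param dim grid dimensions (default `c(12, 12, 12)`).
#' @param voxel_size voxel edge lengths in mm (default `c(3, 3, 3)`).
#' @return a [truth_map()].
#' @export
default_truth_map <- function(dim = c(12, 12, 12), voxel_size = c(3, 3, 3)) {
  levels6 <- c(trw_hierarchy, "none")
  slab <- ceiling(seq_len(dim[1]) / dim[1] * 6)
  labels <- array(levels6[slab][slicer(dim)], dim = dim)
  truth_map(labels, voxel_size)
}

# x-index of every voxel of a grid, in array order
slicer <- function(dim) {
  rep_len(rep(seq_len(dim[1]), times = dim[2] * dim[3]), prod(dim))
}

#' Cohort simulation parameters
#'
#' Defaults reflect the emulated study: 15 usable runs per condition, TR of
#' 1.5 s, a 3 s silent lead-in before a 255 s stimulus (172 volumes per
#' run), and a stimulus-locked signal amplitude equal to the noise sd
#' (`alpha = sigma = 1`).
#'
#' @param n_subjects number of subjects (>= 2; default 15).
#' @param alpha shared-signal amplitude (>= 0; default 1).
#' @param sigma subject noise sd (> 0; default 1).
#' @param tr repetition time in seconds (default 1.5).
#' @param hrf convolve latent time courses with [hrf_double_gamma()]
#'   (default `FALSE`).
#' @param seed integer seed (default 1).
#' @param silence_s silent lead-in in seconds (default 3).
#' @param conditions conditions to simulate, ordered by coherence
#'   (default [trw_hierarchy]).
#' @param latent_fwhm_s temporal FWHM in seconds of the Gaussian filter
#'   applied to latent white noise (default 3).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 15, alpha = 1, sigma = 1, tr = 1.5,
                        hrf = FALSE, seed = 1, silence_s = 3,
                        conditions = trw_hierarchy, latent_fwhm_s = 3) {
  stopifnot(n_subjects >= 2, alpha >= 0, sigma > 0, tr > 0)
  if (is.unsorted(coherence_rank(conditions), strictly = TRUE)) {
    stop("conditions must be ordered by increasing coherence")
  }
  structure(list(n_subjects = as.integer(n_subjects), alpha = alpha,
                 sigma = sigma, tr = tr, hrf = hrf,
                 seed = as.integer(seed), silence_s = silence_s,
                 conditions = conditions, latent_fwhm_s = latent_fwhm_s),
            class = "cohort_spec")
}

# temporally smooth standardized latent noise, T x V
smooth_latent <- function(T_len, V, tr, fwhm_s, hrf_kernel = NULL) {
  x <- matrix(rnorm(T_len * V), T_len, V)
  sigma_tr <- fwhm_s / (2 * sqrt(2 * log(2))) / tr
  if (sigma_tr > 0) {
    r <- max(1L, ceiling(3.5 * sigma_tr))
    w <- exp(-((-r:r)^2) / (2 * sigma_tr^2))
    w <- w / sum(w)
    x <- rbind(x[rep(1, r), , drop = FALSE], x,
               x[rep(T_len, r), , drop = FALSE])
    x <- apply(x, 2, function(col) {
      stats::filter(col, w, sides = 2)[(r + 1):(r + T_len)]
    })
  }
  if (!is.null(hrf_kernel)) x <- convolve_hrf(x, hrf_kernel)
  sds <- apply(x, 2, sd)
  sds[sds == 0] <- 1
  sweep(sweep(x, 2, colMeans(x)), 2, sds, "/")
}

#' Simulate a subject cohort with known TRW structure
#'
#' For a voxel with ground-truth level `L` and condition `c`, each
#' subject's series is `alpha * z + sigma * e` where `z` is a smooth latent
#' time course shared across subjects when `coherence(c) >= coherence(L)`
#' (the condition's coherent segments are long enough for that voxel's
#' TRW) and subject-specific otherwise; `e` is white subject noise.
#' Voxels labelled `"none"` never share. Latents are Gaussian-filtered
#' white noise (temporal FWHM `latent_fwhm_s`), optionally convolved with
#' the canonical HRF, and standardized. Run length is
#' `(silence_s + total_duration) / tr` volumes.
#'
#' @param seg a [segmentation_spec()] (sets the stimulus duration).
#' @param truth a [truth_map()].
#' @param cohort a [cohort_spec()].
#' @return nested list `runs[[condition]][[subject]]` of [bold_run()],
#'   with attributes `truth` and `cohort`.
#' @export
gen_cohort_bold <- function(seg, truth, cohort = cohort_spec()) {
  stopifnot(inherits(seg, "segmentation_spec"),
            inherits(truth, "truth_map"),
            inherits(cohort, "cohort_spec"))
  d <- dim(truth$labels)
  V <- prod(d)
  T_len <- run_volume_count(seg$total_duration, cohort$silence_s,
                            cohort$tr)
  flat <- gen_cohort_flat(V, T_len, truth_labels = as.vector(truth$labels),
                          cohort = cohort)
  runs <- lapply(cohort$conditions, function(cond) {
    lapply(seq_len(cohort$n_subjects), function(s) {
      bold_run(array(t(flat[[cond]][, , s]), dim = c(d, T_len)),
               tr = cohort$tr, voxel_size = truth$voxel_size,
               subject = s, condition = cond)
    })
  })
  names(runs) <- cohort$conditions
  attr(runs, "truth") <- truth
  attr(runs, "cohort") <- cohort
  runs
}

#' Simulate cohort arrays without a spatial grid
#'
#' Core generative model behind [gen_cohort_bold()], producing one
#' `T x V x N` array per condition for an arbitrary set of voxels. Useful
#' for flat-geometry simulations (e.g. global-null cohorts with
#' `alpha = 0`).
#'
#' @param n_voxels number of voxels.
#' @param n_timepoints run length in TRs.
#' @param truth_labels per-voxel truth labels (default all `"none"`).
#' @param cohort a [cohort_spec()].
#' @return named list of `T x V x N` arrays, one per condition.
#' @export
gen_cohort_flat <- function(n_voxels, n_timepoints,
                            truth_labels = rep("none", n_voxels),
                            cohort = cohort_spec()) {
  stopifnot(length(truth_labels) == n_voxels, n_timepoints >= 4)
  set.seed(cohort$seed)
  kern <- if (cohort$hrf) hrf_double_gamma(cohort$tr) else NULL
  rank_truth <- coherence_rank(truth_labels)
  out <- list()
  for (cond in cohort$conditions) {
    shares <- coherence_rank(cond) >= rank_truth
    arr <- array(0, c(n_timepoints, n_voxels, cohort$n_subjects))
    z <- smooth_latent(n_timepoints, n_voxels, cohort$tr,
                       cohort$latent_fwhm_s, kern)
    for (s in seq_len(cohort$n_subjects)) {
      u <- smooth_latent(n_timepoints, n_voxels, cohort$tr,
                         cohort$latent_fwhm_s, kern)
      lat <- z
      lat[, !shares] <- u[, !shares]
      arr[, , s] <- cohort$alpha * lat +
        cohort$sigma * matrix(rnorm(n_timepoints * n_voxels),
                              n_timepoints, n_voxels)
    }
    out[[cond]] <- arr
  }
  out
}

#' Stack a cohort's runs into a condition array
#'
#' Flattens the grid of each subject's [bold_run()] for one condition into
#' a `T x V x N` array for the ISC machinery.
#'
#' @param runs output of [gen_cohort_bold()] (or a list of preprocessed
#'   runs with the same structure).
#' @param condition condition name.
#' @return `T x V x N` array.
#' @export
cohort_array <- function(runs, condition) {
  if (!condition %in% names(runs)) stop("unknown condition '", condition,
                                        "'")
  subj <- runs[[condition]]
  mats <- lapply(subj, run_matrix)
  T_len <- nrow(mats[[1]]); V <- ncol(mats[[1]])
  arr <- array(0, c(T_len, V, length(mats)))
  for (s in seq_along(mats)) arr[, , s] <- mats[[s]]
  arr
}
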