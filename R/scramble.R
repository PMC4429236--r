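#' Cut an audio track at the boundaries of one segmentation level
#'
#' Boundary times are rounded to the nearest sample; segments are half-open
#' so that concatenating them in original order reproduces the track over
#' `[0, total_duration)` exactly.
#'
#' @param track an [audio_track()].
#' @param spec a [segmentation_spec()].
#' @param level level name (e.g. `"measure"`).
#' @return list of [audio_track()] segments in original order.
#' @export
segment_audio <- function(track, spec, level) {
  stopifnot(inherits(track, "audio_track"),
            inherits(spec, "segmentation_spec"))
  if (!level %in% spec$levels) stop("unknown level '", level, "'")
  fs <- track$sample_rate
  if (spec$total_duration > track_duration(track) + 1 / fs) {
    stop("segmentation (", spec$total_duration,
         " s) is longer than the track (", track_duration(track), " s)")
  }
  b <- spec$boundaries[[level]]
  lapply(seq_len(nrow(b)), function(i) {
    i0 <- round(b$start[i] * fs) + 1L
    i1 <- round(b$end[i] * fs)
    audio_track(track$samples[i0:i1], fs)
  })
}

#' Draw a scramble order with no sequential adjacency
#'
#' Samples uniformly (by seeded rejection) over permutations of
#' `0..n-1` in which no element is immediately followed by its successor,
#' i.e. the output never contains the pair `(i, i+1)` in adjacent
#' positions. For `n >= 2` this also excludes the identity order.
#'
#' @param n number of segments.
#' @param seed integer seed; deterministic given the seed.
#' @return object of class `scramble_order` with fields `perm` (0-based
#'   permutation) and `seed`.
#' @export
make_order <- function(n, seed) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  if (n == 1L) {
    perm <- 0L
  } else {
    repeat {
      perm <- sample.int(n) - 1L
      if (!any(diff(perm) == 1L)) break
    }
  }
  structure(list(perm = perm, seed = as.integer(seed)),
            class = "scramble_order")
}

#' @export
print.scramble_order <- function(x, ...) {
  cat("scramble_order (seed ", x$seed, "): ",
      paste(x$perm, collapse = " "), "\n", sep = "")
  invisible(x)
}

as_perm0 <- function(order, n) {
  perm <- if (inherits(order, "scramble_order")) order$perm else
    as.integer(order)
  if (length(perm) != n || !setequal(perm, seq_len(n) - 1L)) {
    stop("order is not a permutation of 0..", n - 1L)
  }
  perm
}

#' Reassemble segments in a scrambled order with crossfades
#'
#' Concatenates segments in the given order using overlap-add with linear
#' fades that sum to unity, so the output duration is
#' `sum(durations) - (n - 1) * crossfade_s` and constant signals pass
#' through the joins unchanged.
#'
#' @param segments list of [audio_track()] sharing one sample rate.
#' @param order a [make_order()] result, a 0-based integer permutation, or
#'   `NULL` for the original order.
#' @param crossfade_s crossfade duration in seconds (default 0.010).
#' @param clip_guard if `TRUE`, clip output into `[-1, 1]`.
#' @return an [audio_track()].
#' @export
reassemble <- function(segments, order = NULL, crossfade_s = 0.010,
                       clip_guard = FALSE) {
  stopifnot(length(segments) >= 1, crossfade_s >= 0)
  fs <- segments[[1L]]$sample_rate
  if (!all(vapply(segments, function(s) s$sample_rate, numeric(1)) == fs)) {
    stop("all segments must share one sample rate")
  }
  n <- length(segments)
  perm <- if (is.null(order)) seq_len(n) - 1L else as_perm0(order, n)
  xs <- lapply(perm + 1L, function(i) segments[[i]]$samples)
  l_cf <- round(crossfade_s * fs)
  if (l_cf > 0 && l_cf >= min(lengths(xs))) {
    stop("crossfade (", l_cf, " samples) is not shorter than the ",
         "shortest segment (", min(lengths(xs)), " samples)")
  }
  out <- xs[[1L]]
  if (n > 1L) {
    up <- if (l_cf > 0) seq_len(l_cf) / (l_cf + 1) else numeric(0)
    for (i in 2L:n) {
      seg <- xs[[i]]
      if (l_cf > 0) {
        tail_idx <- (length(out) - l_cf + 1L):length(out)
        out[tail_idx] <- out[tail_idx] * (1 - up) + seg[seq_len(l_cf)] * up
        out <- c(out, seg[-seq_len(l_cf)])
      } else {
        out <- c(out, seg)
      }
    }
  }
  if (clip_guard) out <- pmax(-1, pmin(1, out))
  audio_track(out, fs)
}

#' Scramble a track at one structural level
#'
#' Convenience composition of [segment_audio()], [make_order()], and
#' [reassemble()].
#'
#' @param track an [audio_track()].
#' @param spec a [segmentation_spec()].
#' @param level level to scramble at.
#' @param seed integer seed for the order.
#' @param crossfade_s crossfade in seconds.
#' @return an [audio_track()] with attribute `order`.
#' @export
scramble_track <- function(track, spec, level, seed, crossfade_s = 0.010) {
  segs <- segment_audio(track, spec, level)
  ord <- make_order(length(segs), seed)
  out <- reassemble(segs, ord, crossfade_s = crossfade_s)
  attr(out, "order") <- ord
  out
}

#' Dynamic range compression
#'
#' Feed-forward compressor: a peak detector (instantaneous rise,
#' first-order release decay) drives the static gain law
#' `out_db = threshold_db + (in_db - threshold_db) / ratio` above
#' threshold, and the gain is smoothed first-order with the attack time
#' constant while reduction deepens and the release time constant while it
#' recovers. With `makeup = TRUE` the output is rescaled to the input RMS.
#'
#' @param track an [audio_track()].
#' @param threshold_db compression threshold in dBFS (default -20).
#' @param ratio compression ratio (>= 1; default 4).
#' @param attack_s attack time constant in seconds (default 0.010).
#' @param release_s release time constant in seconds (default 0.100).
#' @param makeup apply RMS-matched makeup gain (default `FALSE`).
#' @return compressed [audio_track()].
#' @export
compress_dynamics <- function(track, threshold_db = -20, ratio = 4,
                              attack_s = 0.010, release_s = 0.100,
                              makeup = FALSE) {
  stopifnot(inherits(track, "audio_track"))
  if (ratio < 1) stop("compression ratio must be >= 1")
  x <- track$samples
  if (!length(x)) return(track)
  fs <- track$sample_rate
  a_att <- 1 - exp(-1 / (fs * attack_s))
  a_rel <- 1 - exp(-1 / (fs * release_s))
  y <- x * compressor_gain_cpp(abs(x), a_att, a_rel, threshold_db, ratio)
  if (makeup) {
    rms_in <- sqrt(mean(x^2))
    rms_out <- sqrt(mean(y^2))
    if (rms_out > 0) y <- y * (rms_in / rms_out)
  }
  audio_track(y, fs)
}

#' Build the full stimulus condition set
#'
#' From an intact track and its segmentation, constructs the five
#' conditions: scrambled at each level, the time-reversed waveform, and the
#' intact original, optionally dynamic-range compressed (scrambled
#' conditions only, to reduce loudness contrasts between reordered
#' segments).
#'
#' @param track intact [audio_track()].
#' @param spec a [segmentation_spec()].
#' @param seed integer seed; each level's order uses `seed + level index`.
#' @param crossfade_s crossfade in seconds.
#' @param compress apply [compress_dynamics()] to scrambled conditions.
#' @return named list of [audio_track()] (backward, one per level, intact).
#' @export
build_conditions <- function(track, spec, seed, crossfade_s = 0.010,
                             compress = TRUE) {
  out <- list(backward = reverse_track(track))
  for (i in seq_along(spec$levels)) {
    lev <- spec$levels[i]
    scr <- scramble_track(track, spec, lev, seed + i, crossfade_s)
    if (compress) scr <- compress_dynamics(scr, makeup = TRUE)
    out[[lev]] <- scr
  }
  out$intact <- track
  out
}
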