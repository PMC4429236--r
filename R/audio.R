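#' Audio track container
#'
#' A mono (or multi-channel) waveform with amplitudes in `[-1, 1]` and a
#' sampling rate in Hz. Multi-channel tracks store samples as a matrix with
#' one column per channel; everything in this package operates on mono.
#'
#' @param samples numeric vector (mono) of sample amplitudes.
#' @param sample_rate sampling rate in Hz.
#' @return object of class `audio_track`.
#' @export
audio_track <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), sample_rate > 0)
  if (any(!is.finite(samples))) stop("audio samples must be finite")
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate),
            class = "audio_track")
}

#' @export
print.audio_track <- function(x, ...) {
  cat(sprintf("audio_track: %.3f s at %g Hz (%d samples, peak %.3f)\n",
              track_duration(x), x$sample_rate, length(x$samples),
              max(abs(x$samples), 0)))
  invisible(x)
}

#' Track duration in seconds
#' @param track an [audio_track()].
#' @return duration in seconds.
#' @export
track_duration <- function(track) length(track$samples) / track$sample_rate

#' Time-reverse a waveform
#'
#' Returns the sample-reversed track (the "backward" stimulus condition).
#' Reversal is an involution and preserves the magnitude spectrum.
#'
#' @param track an [audio_track()].
#' @return reversed [audio_track()].
#' @export
reverse_track <- function(track) {
  stopifnot(inherits(track, "audio_track"))
  if (!length(track$samples)) stop("cannot reverse an empty track")
  audio_track(rev(track$samples), track$sample_rate)
}

## ---- WAV I/O (RIFF/WAVE, 16-bit PCM and IEEE float32) ----

#' Write a WAV file
#'
#' Writes mono 16-bit PCM (`format = "pcm16"`) or 32-bit IEEE float
#' (`format = "float32"`). Samples outside `[-1, 1]` are clipped for PCM.
#'
#' @param track an [audio_track()].
#' @param path output path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(track, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  x <- track$samples
  fs <- as.integer(round(track$sample_rate))
  n_ch <- 1L
  if (format == "pcm16") {
    bits <- 16L; fmt_code <- 1L
    data <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
    data_size <- 2L * length(data)
  } else {
    bits <- 32L; fmt_code <- 3L
    data <- x
    data_size <- 4L * length(data)
  }
  block_align <- n_ch * bits %/% 8L
  byte_rate <- fs * block_align
  con <- file(path, "wb")
  on.exit(close(con))
  wr_str <- function(s) writeBin(charToRaw(s), con)
  wr_u32 <- function(v) writeBin(as.integer(v), con, size = 4,
                                 endian = "little")
  wr_u16 <- function(v) writeBin(as.integer(v), con, size = 2,
                                 endian = "little")
  fact_size <- if (fmt_code == 3L) 12L else 0L
  wr_str("RIFF"); wr_u32(4L + 24L + fact_size + 8L + data_size)
  wr_str("WAVE")
  wr_str("fmt "); wr_u32(16L)
  wr_u16(fmt_code); wr_u16(n_ch); wr_u32(fs); wr_u32(byte_rate)
  wr_u16(block_align); wr_u16(bits)
  if (fmt_code == 3L) {
    wr_str("fact"); wr_u32(4L); wr_u32(length(x))
  }
  wr_str("data"); wr_u32(data_size)
  if (format == "pcm16") {
    writeBin(data, con, size = 2, endian = "little")
  } else {
    writeBin(data, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Reads mono or multi-channel 16-bit PCM or 32-bit float WAV; multi-channel
#' input is averaged down to mono.
#'
#' @param path WAV file path.
#' @return an [audio_track()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) rawToChar(readBin(con, "raw", n))
  rd_u32 <- function() readBin(con, "integer", size = 4, endian = "little")
  rd_u16 <- function() readBin(con, "integer", size = 2, endian = "little",
                               signed = FALSE)
  if (rd_str(4) != "RIFF") stop("not a RIFF file")
  rd_u32()
  if (rd_str(4) != "WAVE") stop("not a WAVE file")
  fmt_code <- NA_integer_; n_ch <- NA_integer_; fs <- NA_integer_
  bits <- NA_integer_; samples <- NULL
  repeat {
    id <- readBin(con, "raw", 4)
    if (length(id) < 4) break
    id <- rawToChar(id)
    size <- rd_u32()
    if (id == "fmt ") {
      fmt_code <- rd_u16(); n_ch <- rd_u16(); fs <- rd_u32()
      rd_u32(); rd_u16(); bits <- rd_u16()
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      if (fmt_code == 1L && bits == 16L) {
        samples <- readBin(con, "integer", n = size %/% 2, size = 2,
                           endian = "little") / 32767
      } else if (fmt_code == 3L && bits == 32L) {
        samples <- readBin(con, "double", n = size %/% 4, size = 4,
                           endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt_code, ", ", bits,
             " bits)")
      }
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (n_ch > 1L) {
    samples <- rowMeans(matrix(samples, ncol = n_ch, byrow = TRUE))
  }
  audio_track(samples, fs)
}

## ---- synthetic stimulus audio ----

#' Generate synthetic stimulus audio from a segmentation
#'
#' Synthesizes one tone event per finest-level segment (a "measure"), with
#' per-section pitch and amplitude profiles and per-measure accents, so that
#' envelope structure exists at every hierarchical level. Each measure is a
#' sine tone shaped by an attack/decay envelope. The designed instantaneous
#' amplitude is retained in the `amp` attribute for envelope-recovery
#' checks; [designed_envelope()] resamples it at the BOLD sampling rate.
#'
#' @param spec a [segmentation_spec()].
#' @param sample_rate sampling rate in Hz (>= 8000; default 12000 so that a
#'   4--4000 Hz analysis band is feasible).
#' @param seed integer seed.
#' @param amplitude_scale overall amplitude scale; 0 yields a silent track.
#' @return an [audio_track()] with attribute `amp` (designed per-sample
#'   amplitude).
#' @export
gen_audio <- function(spec, sample_rate = 12000, seed = 1,
                      amplitude_scale = 0.8) {
  stopifnot(inherits(spec, "segmentation_spec"))
  if (sample_rate < 8000) stop("sample_rate must be >= 8000 Hz")
  if (!length(spec$levels)) stop("empty segmentation spec")
  set.seed(as.integer(seed))
  fs <- sample_rate
  n_total <- round(spec$total_duration * fs)
  x <- numeric(n_total)
  amp <- numeric(n_total)

  measures <- spec$boundaries[[1L]]
  coarse <- spec$boundaries[[length(spec$levels)]]
  # per-section pitch base (semitones over A3) and dynamic level
  sec_pitch <- 220 * 2^(sample(0:12, nrow(coarse), replace = TRUE) / 12)
  sec_amp <- runif(nrow(coarse), 0.25, 1.0)
  # within-section crescendo/diminuendo (slow dynamic structure)
  sec_ramp <- sample(c(-0.4, 0.4), nrow(coarse), replace = TRUE)
  mid <- (measures$start + measures$end) / 2
  sec_of <- findInterval(mid, coarse$start)
  sec_frac <- (mid - coarse$start[sec_of]) /
    (coarse$end[sec_of] - coarse$start[sec_of])

  for (i in seq_len(nrow(measures))) {
    i0 <- round(measures$start[i] * fs) + 1L
    i1 <- round(measures$end[i] * fs)
    if (i1 < i0) next
    n <- i1 - i0 + 1L
    f <- sec_pitch[sec_of[i]] * 2^(sample(c(0, 2, 4, 7, 9), 1) / 12)
    accent <- runif(1, 0.7, 1.0)
    dyn <- 1 + sec_ramp[sec_of[i]] * (sec_frac[i] - 0.5)
    a <- sec_amp[sec_of[i]] * dyn * accent
    tt <- seq_len(n) / fs
    n_att <- max(1L, round(0.05 * n))
    env <- c(seq(0, 1, length.out = n_att),
             exp(-3 * seq_len(n - n_att) / n)) # attack then decay
    env <- env[seq_len(n)]
    amp[i0:i1] <- a * env
    x[i0:i1] <- a * env * sin(2 * pi * f * tt)
  }
  x <- x * amplitude_scale
  amp <- amp * amplitude_scale
  out <- audio_track(x, fs)
  attr(out, "amp") <- amp
  out
}

#' Designed amplitude profile at the BOLD sampling rate
#'
#' Averages the per-sample designed amplitude of a [gen_audio()] track with
#' a Hann window of width two TRs centered on the envelope sampling
#' instants `t = 0, tr, 2 tr, ...` (edge windows truncated). The window
#' width matches the main lobe of the anti-aliasing low-pass used when the
#' extracted envelope is decimated to the BOLD rate, so this is the profile
#' the extracted envelope should recover.
#'
#' @param track a track produced by [gen_audio()].
#' @param tr sampling interval in seconds.
#' @return numeric vector, one value per TR.
#' @export
designed_envelope <- function(track, tr = 1.5) {
  amp <- attr(track, "amp")
  if (is.null(amp)) stop("track has no designed amplitude profile")
  per <- round(tr * track$sample_rate)
  n <- floor(length(amp) / per)
  hw <- per
  w <- 0.5 * (1 - cos(2 * pi * seq_len(2 * hw + 1) / (2 * hw + 2)))
  vapply(seq_len(n), function(k) {
    center <- (k - 1L) * per + 1L
    lo <- max(1L, center - hw)
    hi <- min(length(amp), center + hw)
    ww <- w[(lo - center + hw + 1L):(hi - center + hw + 1L)]
    sum(amp[lo:hi] * ww) / sum(ww)
  }, numeric(1))
}
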