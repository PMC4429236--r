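two_segment_spec <- function() {
  segmentation_spec(2, list(half = data.frame(start = c(0, 1),
                                              end = c(1, 2))))
}

test_that("segmentation partitions the track exactly", {
  set.seed(1)
  tr <- audio_track(runif(2 * 8000, -1, 1), 8000)
  segs <- segment_audio(tr, two_segment_spec(), "half")
  expect_length(segs, 2)
  expect_length(segs[[1]]$samples, 8000)
  expect_identical(c(segs[[1]]$samples, segs[[2]]$samples), tr$samples)

  # one-segment level returns the whole track
  whole <- segmentation_spec(2, list(all = data.frame(start = 0, end = 2)))
  seg1 <- segment_audio(tr, whole, "all")
  expect_identical(seg1[[1]]$samples, tr$samples)

  # irregular boundaries still partition sample-exactly
  spec <- gen_segmentation(2, list(m = list(mean = 0.23, sd = 0.05)),
                           seed = 3)
  segs <- segment_audio(tr, spec, "m")
  expect_equal(sum(lengths(lapply(segs, `[[`, "samples"))), 16000)
  expect_error(segment_audio(tr, two_segment_spec(), "nope"), "unknown")
})

test_that("scramble orders are valid permutations without adjacencies", {
  o1 <- make_order(1, seed = 5)
  expect_identical(o1$perm, 0L)
  o2 <- make_order(2, seed = 5)
  expect_identical(o2$perm, c(1L, 0L)) # only valid order for n = 2
  # n = 3: sampled orders always in the brute-force valid set
  vs3 <- apply(valid_orders(3), 1, order_key)
  expect_setequal(vs3, c("0,2,1", "1,0,2", "2,1,0"))
  draws <- vapply(1:200, function(s) order_key(make_order(3, s)$perm),
                  character(1))
  expect_true(all(draws %in% vs3))
  # deterministic and never the identity for n >= 2
  expect_identical(make_order(8, 3)$perm, make_order(8, 3)$perm)
  for (s in 1:50) {
    o <- make_order(5, s)$perm
    expect_false(identical(o, 0:4))
    expect_false(any(diff(o) == 1L))
  }
})

test_that("reassembly overlap-add has exact length and unity crossfades", {
  fs <- 44100
  seg <- function(v) audio_track(rep(v, fs), fs)
  out <- reassemble(list(seg(0.3), seg(0.5)), c(0L, 1L),
                    crossfade_s = 0.010)
  expect_length(out$samples, 2 * fs - 441) # 87,759 samples
  # constant-1 segments: linear fades sum to one across the join
  ones <- reassemble(list(seg(1), seg(1)), c(0L, 1L), crossfade_s = 0.010)
  expect_lt(max(abs(ones$samples - 1)), 1e-12)
  # zero crossfade with identity order is bit-exact concatenation
  set.seed(2)
  a <- audio_track(runif(1000, -1, 1), 1000)
  b <- audio_track(runif(1000, -1, 1), 1000)
  cat0 <- reassemble(list(a, b), NULL, crossfade_s = 0)
  expect_identical(cat0$samples, c(a$samples, b$samples))
  expect_error(reassemble(list(a, b), NULL, crossfade_s = 1.5), "shortest")
})

test_that("scrambling preserves audio content energy", {
  spec <- gen_segmentation(30, list(m = list(mean = 1.3, sd = 0.12)),
                           seed = 1)
  aud <- gen_audio(spec, seed = 4)
  segs <- segment_audio(aud, spec, "m")
  e_segs <- sum(vapply(segs, function(s) sum(s$samples^2), numeric(1)))
  scr <- scramble_track(aud, spec, "m", seed = 6)
  expect_lt(abs(sum(scr$samples^2) - e_segs) / e_segs, 0.01)
})

test_that("section-level scrambling preserves within-section order", {
  spec <- study_segmentation(1)
  aud <- gen_audio(spec, seed = 2)
  segs <- segment_audio(aud, spec, "section")
  ord <- make_order(length(segs), seed = 9)
  out <- reassemble(segs, ord, crossfade_s = 0) # no fades: exact blocks
  pos <- 1L
  for (idx in ord$perm + 1L) {
    n <- length(segs[[idx]]$samples)
    expect_identical(out$samples[pos:(pos + n - 1L)], segs[[idx]]$samples)
    pos <- pos + n
  }
})

test_that("compressor follows the static gain law on steady tones", {
  fs <- 12000
  tone <- function(a) audio_track(a * sin(2 * pi * 440 * seq_len(2 * fs) /
                                            fs), fs)
  # -6 dBFS input, threshold -20, ratio 4 -> steady-state peak ~ -16.5 dBFS
  y <- compress_dynamics(tone(0.5), threshold_db = -20, ratio = 4)
  peak_db <- 20 * log10(max(abs(y$samples[fs:(2 * fs)])))
  expect_lt(abs(peak_db - (-16.5)), 0.5)
  # below threshold, makeup off: unchanged
  q <- tone(0.05)
  expect_lt(max(abs(compress_dynamics(q)$samples - q$samples)), 1e-6)
  expect_error(compress_dynamics(q, ratio = 0.5), "ratio")
})

test_that("compression reduces loud/soft contrast", {
  fs <- 8000
  loud <- 0.8 * sin(2 * pi * 330 * seq_len(fs) / fs)
  soft <- 0.05 * sin(2 * pi * 330 * seq_len(fs) / fs)
  x <- audio_track(c(loud, soft, loud, soft), fs)
  y <- compress_dynamics(x, makeup = TRUE)
  rms <- function(v) sqrt(mean(v^2))
  seg <- function(t, k) t$samples[((k - 1) * fs + 1):(k * fs)]
  ratio_in <- rms(seg(x, 1)) / rms(seg(x, 2))
  ratio_out <- rms(seg(y, 1)) / rms(seg(y, 2))
  expect_lt(ratio_out, ratio_in)
})
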