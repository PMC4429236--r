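# segment-duration parameters of the emulated 4'15" stimulus
study_level_params <- function() {
  list(measure = list(mean = 1.29, sd = 0.12),
       phrase = list(mean = 6.32, sd = 1.91),
       section = list(mean = 38.28, sd = 12.46))
}

study_segmentation <- function(seed = 1) {
  gen_segmentation(255, study_level_params(), seed = seed)
}

# all permutations of 1..n (insertion construction)
perms_all <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- perms_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- p + (p >= k)
    cbind(k, rest, deparse.level = 0)
  }))
}

# brute-force set of valid scramble orders (0-based, no (i, i+1) adjacency)
valid_orders <- function(n) {
  all0 <- perms_all(n) - 1L
  ok <- apply(all0, 1, function(o) !any(diff(o) == 1L))
  m <- all0[ok, , drop = FALSE]
  m[order(apply(m, 1, paste, collapse = ",")), , drop = FALSE]
}

order_key <- function(o) paste(o, collapse = ",")
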