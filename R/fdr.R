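#' False-discovery-rate threshold over sorted p-values
#'
#' Sorts the p-values in ascending order and selects the maximum `k` such
#' that `p_(k) < (k / N) * q_star` (strict inequality). The significance
#' mask contains every test with `p <= p_(k)`. With
#' `by_correction = TRUE`, `q_star` is replaced by
#' `q_star / sum(1/i, i = 1..N)`, the correction valid under arbitrary
#' dependence.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @param q_star FDR level (default 0.05).
#' @param by_correction apply the harmonic-sum dependence correction
#'   (default `FALSE`).
#' @return object of class `fdr_decision`: list with `k` (0 when nothing
#'   passes), `p_threshold` (`NA` when nothing passes), `mask` (logical,
#'   original order), `q_star`, `n`, `by_correction`.
#' @examples
#' fdr_threshold(c(0.001, 0.02, 0.03, 0.5))
#' @export
fdr_threshold <- function(pvalues, q_star = 0.05, by_correction = FALSE) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  n <- length(pvalues)
  q_eff <- if (by_correction) q_star / sum(1 / seq_len(n)) else q_star
  ps <- sort(pvalues)
  pass <- ps < (seq_len(n) / n) * q_eff
  k <- if (any(pass)) max(which(pass)) else 0L
  p_thr <- if (k > 0L) ps[k] else NA_real_
  mask <- if (k > 0L) pvalues <= p_thr else rep(FALSE, n)
  structure(list(k = k, p_threshold = p_thr, mask = mask, q_star = q_star,
                 n = n, by_correction = by_correction),
            class = "fdr_decision")
}

#' @export
print.fdr_decision <- function(x, ...) {
  cat(sprintf(
    "fdr_decision: %d / %d rejected at q* = %g%s (p* = %s)\n",
    sum(x$mask), x$n, x$q_star,
    if (x$by_correction) " [dependence-corrected]" else "",
    if (is.na(x$p_threshold)) "none" else format(x$p_threshold)))
  invisible(x)
}
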