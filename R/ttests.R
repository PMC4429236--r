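#' One-tailed paired t-test (A greater than B)
#'
#' Paired t on the differences `x - y`, testing the one-sided alternative
#' that condition A exceeds condition B. When the differences have zero
#' variance the statistic is degenerate: `t = 0, p = 0.5` if all
#' differences are zero, otherwise `t = +/-Inf` with `p = 0` or `1`; the
#' `degenerate` flag is set in either case.
#'
#' @param x per-subject values, condition A.
#' @param y per-subject values, condition B (same length, >= 3).
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
paired_ttest_onetailed <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  n <- length(d)
  s <- sd(d)
  if (s == 0) {
    m <- mean(d)
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 0.5 else if (m > 0) 0 else 1
    return(list(t = t_stat, p = p, df = n - 1, degenerate = TRUE))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, p = pt(t_stat, df = n - 1, lower.tail = FALSE),
       df = n - 1, degenerate = FALSE)
}

#' One-tailed Welch two-sample t-test (group 1 greater than group 2)
#'
#' Welch t-test on raw correlation coefficients (no Fisher transform by
#' default, matching the reported analysis; `fisher_z = TRUE` transforms
#' both groups first).
#'
#' @param x group-1 values (length >= 2).
#' @param y group-2 values (length >= 2).
#' @param fisher_z apply `atanh` before testing (default `FALSE`).
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @export
twosample_ttest_onetailed <- function(x, y, fisher_z = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (fisher_z) {
    x <- atanh(pmin(pmax(x, -1 + 1e-15), 1 - 1e-15))
    y <- atanh(pmin(pmax(y, -1 + 1e-15), 1 - 1e-15))
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    dm <- mean(x) - mean(y)
    t_stat <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm == 0) 0.5 else if (dm > 0) 0 else 1
    return(list(t = t_stat, p = p, df = NA_real_, degenerate = TRUE))
  }
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t_stat, p = pt(t_stat, df = df, lower.tail = FALSE), df = df,
       degenerate = FALSE)
}

#' Regression of per-subject ISC on a covariate
#'
#' Ordinary least squares of per-subject leave-one-out correlations on a
#' per-subject covariate (e.g. stimulus familiarity ratings); reports the
#' slope and coefficient of determination.
#'
#' @param r per-subject correlation values (length >= 3).
#' @param covariate per-subject covariate scores (non-constant).
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
covariate_regression <- function(r, covariate) {
  stopifnot(length(r) == length(covariate))
  if (length(r) < 3) stop("covariate regression needs >= 3 subjects")
  if (stats::var(covariate) == 0) stop("covariate is constant")
  fit <- lm(r ~ covariate)
  tss <- sum((r - mean(r))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(stats::residuals(fit)^2) / tss
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2)
}
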