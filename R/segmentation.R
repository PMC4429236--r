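#' Segmentation specification
#'
#' A `segmentation_spec` describes the nested structural levels of a
#' stimulus: within each level, half-open intervals `[start_s, end_s)` tile
#' `[0, total_duration)` without gap or overlap, and every boundary at a
#' coarser level coincides with a boundary at every finer level (strict
#' nesting). Levels are stored finest first (e.g. measure, phrase, section).
#'
#' @param total_duration total stimulus duration in seconds.
#' @param boundaries named list (finest level first); each element a
#'   data.frame with numeric columns `start` and `end` in seconds.
#' @return object of class `segmentation_spec`.
#' @export
segmentation_spec <- function(total_duration, boundaries) {
  spec <- structure(
    list(total_duration = total_duration,
         levels = names(boundaries),
         boundaries = boundaries),
    class = "segmentation_spec")
  validate_segmentation(spec)
  spec
}

#' Validate a segmentation specification
#'
#' Checks tiling (no gaps/overlaps), positive durations, and strict nesting
#' of coarser levels within finer ones.
#'
#' @param spec a [segmentation_spec()].
#' @param tol numeric tolerance in seconds for boundary comparisons.
#' @return `spec`, invisibly; errors if any invariant fails.
#' @export
validate_segmentation <- function(spec, tol = 1e-9) {
  stopifnot(inherits(spec, "segmentation_spec"), spec$total_duration > 0)
  for (lev in spec$levels) {
    b <- spec$boundaries[[lev]]
    stopifnot(is.data.frame(b), all(c("start", "end") %in% names(b)))
    if (any(b$end - b$start <= 0)) {
      stop("level '", lev, "' contains a non-positive duration segment")
    }
    if (abs(b$start[1]) > tol ||
        abs(b$end[nrow(b)] - spec$total_duration) > tol) {
      stop("level '", lev, "' does not span [0, total_duration)")
    }
    if (nrow(b) > 1 && any(abs(b$start[-1] - b$end[-nrow(b)]) > tol)) {
      stop("level '", lev, "' has gaps or overlaps")
    }
  }
  # strict nesting: every boundary of a coarser level is a boundary of every
  # finer level
  if (length(spec$levels) > 1) {
    for (i in seq_along(spec$levels)[-1]) {
      coarse <- spec$boundaries[[spec$levels[i]]]
      fine <- spec$boundaries[[spec$levels[i - 1L]]]
      fine_pts <- c(fine$start, spec$total_duration)
      for (pt in c(coarse$start, spec$total_duration)) {
        if (min(abs(fine_pts - pt)) > tol) {
          stop("boundary at ", pt, " s of level '", spec$levels[i],
               "' does not coincide with a '", spec$levels[i - 1L],
               "' boundary")
        }
      }
    }
  }
  invisible(spec)
}

#' @export
print.segmentation_spec <- function(x, ...) {
  cat("segmentation_spec:", x$total_duration, "s\n")
  for (lev in x$levels) {
    b <- x$boundaries[[lev]]
    d <- b$end - b$start
    cat(sprintf("  %-8s n = %3d  mean = %6.2f s  sd = %5.2f s\n",
                lev, nrow(b), mean(d), sd(d)))
  }
  invisible(x)
}

#' Number of segments at a level
#' @param spec a [segmentation_spec()].
#' @param level level name.
#' @return integer count.
#' @export
n_segments <- function(spec, level) {
  if (!level %in% spec$levels) stop("unknown level '", level, "'")
  nrow(spec$boundaries[[level]])
}

#' Generate a nested random segmentation
#'
#' Draws segment durations per level from a gamma distribution matched to
#' the requested mean and sd, rescaled to tile the total duration exactly.
#' The segment count at each level is fixed at `round(total / mean)`.
#' Coarser levels are built by grouping whole finer-level units: coarse
#' boundaries are snapped to the nearest finer-level boundary, which
#' guarantees strict nesting by construction.
#'
#' @param total_duration total duration in seconds.
#' @param level_params named list, finest level first; each element
#'   `list(mean = , sd = )` in seconds.
#' @param seed integer seed; the output is deterministic given the seed.
#' @return a [segmentation_spec()].
#' @examples
#' spec <- gen_segmentation(255, list(
#'   measure = list(mean = 1.29, sd = 0.12),
#'   phrase  = list(mean = 6.32, sd = 1.91),
#'   section = list(mean = 38.28, sd = 12.46)), seed = 1)
#' @export
gen_segmentation <- function(total_duration, level_params, seed) {
  stopifnot(total_duration > 0, length(level_params) >= 1)
  means <- vapply(level_params, function(p) p$mean, numeric(1))
  sds <- vapply(level_params, function(p) p$sd, numeric(1))
  if (any(means <= 0) || any(sds < 0)) {
    stop("segment duration means must be positive and sds non-negative")
  }
  if (is.unsorted(means, strictly = TRUE)) {
    stop("infeasible level parameters: levels must be ordered finest ",
         "first with strictly increasing mean durations")
  }
  if (any(means > total_duration * 2)) {
    stop("infeasible level parameters: mean duration exceeds total duration")
  }
  set.seed(as.integer(seed))

  draw_durations <- function(k, m, s) {
    if (k == 1L) return(total_duration)
    d <- if (s <= 0) rep(m, k) else {
      shape <- (m / s)^2
      rgamma(k, shape = shape, rate = shape / m)
    }
    d * (total_duration / sum(d))
  }

  boundaries <- list()
  fine_pts <- NULL # interior boundaries of the finer level
  for (i in seq_along(level_params)) {
    k <- max(1L, as.integer(round(total_duration / means[i])))
    d <- draw_durations(k, means[i], sds[i])
    cuts <- cumsum(d)[-k] # interior boundaries
    if (i > 1L && length(cuts)) {
      # snap each coarse boundary to the nearest unused finer boundary
      snapped <- numeric(0)
      avail <- fine_pts
      for (ct in cuts) {
        j <- which.min(abs(avail - ct))
        snapped <- c(snapped, avail[j])
        avail <- avail[-j]
      }
      cuts <- sort(snapped)
    }
    starts <- c(0, cuts)
    ends <- c(cuts, total_duration)
    boundaries[[names(level_params)[i]]] <- data.frame(start = starts,
                                                       end = ends)
    fine_pts <- if (i == 1L) cuts else cuts
  }
  segmentation_spec(total_duration, boundaries)
}

#' Write a segmentation to TSV
#'
#' Columns: `level`, `index` (0-based), `start_s`, `end_s`.
#'
#' @param spec a [segmentation_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_segmentation_tsv <- function(spec, path) {
  rows <- do.call(rbind, lapply(spec$levels, function(lev) {
    b <- spec$boundaries[[lev]]
    data.frame(level = lev, index = seq_len(nrow(b)) - 1L,
               start_s = b$start, end_s = b$end)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a segmentation from TSV
#'
#' Inverse of [write_segmentation_tsv()]. Levels are ordered by decreasing
#' segment count (finest first).
#'
#' @param path TSV path with columns `level`, `index`, `start_s`, `end_s`.
#' @return a [segmentation_spec()].
#' @export
read_segmentation_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("level", "index", "start_s", "end_s") %in% names(tab)))
  counts <- sort(table(tab$level), decreasing = TRUE)
  boundaries <- lapply(names(counts), function(lev) {
    b <- tab[tab$level == lev, ]
    b <- b[order(b$index), ]
    data.frame(start = b$start_s, end = b$end_s)
  })
  names(boundaries) <- names(counts)
  segmentation_spec(max(tab$end_s), boundaries)
}
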