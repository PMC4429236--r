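#' Classify voxels by shortest reliable temporal structure
#'
#' Each voxel is labelled with the lowest-coherence condition in which its
#' response is significantly reliable; voxels significant nowhere are
#' labelled `"none"`. A nesting-violation flag is set for voxels that are
#' not significant in some condition of higher coherence than their label
#' (e.g. significant for measures and sections but not phrases) — the
#' "shortest significant" rule is applied literally, and violations are
#' exposed rather than hidden.
#'
#' @param masks named list of logical arrays/vectors (one per condition,
#'   shared shape): `TRUE` where the condition's ISC is significant.
#' @param hierarchy condition names ordered by increasing coherence
#'   (default [trw_hierarchy], restricted to the masks supplied).
#' @return object of class `trw_map`: list with `labels` (character, same
#'   shape as the masks), `violation` (logical, same shape), `hierarchy`.
#' @export
classify_trw <- function(masks, hierarchy = trw_hierarchy) {
  hierarchy <- hierarchy[hierarchy %in% names(masks)]
  if (!length(hierarchy)) stop("no mask matches the hierarchy")
  if (!all(names(masks) %in% hierarchy)) {
    stop("hierarchy does not cover all masks: ",
         paste(setdiff(names(masks), hierarchy), collapse = ", "))
  }
  dims <- lapply(masks, function(m) if (is.null(dim(m))) length(m) else
    dim(m))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("masks do not share one grid")
  }
  M <- vapply(hierarchy, function(h) as.vector(masks[[h]]),
              logical(length(as.vector(masks[[1]]))))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1)
  first_sig <- apply(M, 1, function(row) {
    w <- which(row)
    if (length(w)) w[1] else NA_integer_
  })
  labels <- ifelse(is.na(first_sig), "none", hierarchy[first_sig])
  violation <- vapply(seq_len(nrow(M)), function(v) {
    if (is.na(first_sig[v])) return(FALSE)
    above <- M[v, seq(first_sig[v], ncol(M)), drop = TRUE]
    !all(above)
  }, logical(1))
  shape <- dims[[1]]
  if (length(shape) > 1) {
    labels <- array(labels, dim = shape)
    violation <- array(violation, dim = shape)
  }
  structure(list(labels = labels, violation = violation,
                 hierarchy = hierarchy),
            class = "trw_map")
}

#' @export
print.trw_map <- function(x, ...) {
  cat("trw_map:", length(as.vector(x$labels)), "voxels\n")
  print(trw_summary(x)$counts)
  invisible(x)
}

#' Label counts and violation rate of a TRW map
#'
#' @param map a [classify_trw()] result.
#' @return list with `counts` (named integer vector over
#'   `hierarchy + "none"`), `n_violation`, `violation_rate`.
#' @export
trw_summary <- function(map) {
  stopifnot(inherits(map, "trw_map"))
  lv <- c(map$hierarchy, "none")
  counts <- table(factor(as.vector(map$labels), levels = lv))
  nv <- sum(map$violation)
  n <- length(as.vector(map$labels))
  list(counts = counts, n_violation = nv,
       violation_rate = if (n) nv / n else 0)
}

#' Score a TRW map against ground truth
#'
#' Exact-label accuracy, adjacent-label accuracy (predicted label within
#' one step of the truth in the ordering `hierarchy + "none"`), and the
#' truth-by-predicted confusion matrix.
#'
#' @param map a [classify_trw()] result.
#' @param truth a [truth_map()] (or character array of labels) on the same
#'   grid.
#' @return list with `accuracy`, `adjacent_accuracy`, `confusion`.
#' @export
score_against_truth <- function(map, truth) {
  stopifnot(inherits(map, "trw_map"))
  truth_labels <- if (inherits(truth, "truth_map")) truth$labels else truth
  pred <- as.vector(map$labels)
  tru <- as.vector(truth_labels)
  if (length(pred) != length(tru)) stop("grid mismatch")
  lv <- unique(c(map$hierarchy, "none", tru))
  ord <- c(trw_hierarchy[trw_hierarchy %in% lv],
           setdiff(lv, trw_hierarchy))
  confusion <- table(truth = factor(tru, ord), predicted = factor(pred, ord))
  pr <- match(pred, ord); tr <- match(tru, ord)
  list(accuracy = mean(pred == tru),
       adjacent_accuracy = mean(abs(pr - tr) <= 1),
       confusion = confusion)
}
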