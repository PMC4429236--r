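mask_set <- function(patterns) {
  # patterns: list of logical length-5 vectors (per-voxel rows)
  m <- do.call(rbind, patterns)
  out <- lapply(seq_along(trw_hierarchy), function(i) m[, i])
  names(out) <- trw_hierarchy
  out
}

test_that("voxels are labelled by the shortest reliable condition", {
  masks <- mask_set(list(
    rep(TRUE, 5),                      # all conditions -> backward
    c(FALSE, FALSE, FALSE, FALSE, TRUE), # only intact -> intact
    rep(FALSE, 5),                     # nowhere -> none
    c(FALSE, TRUE, FALSE, TRUE, TRUE), # measure + section (+intact)
    c(FALSE, FALSE, TRUE, TRUE, TRUE)  # phrase upward, nested
  ))
  map <- classify_trw(masks)
  expect_equal(as.vector(map$labels),
               c("backward", "intact", "none", "measure", "phrase"))
  expect_equal(as.vector(map$violation),
               c(FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("classification is monotone under added low-level significance", {
  set.seed(41)
  for (i in 1:25) {
    pat <- runif(5) < 0.5
    base <- classify_trw(mask_set(list(pat)))
    lowered <- pat
    off <- which(!pat)
    if (!length(off)) next
    lowered[off[1]] <- TRUE
    new <- classify_trw(mask_set(list(lowered)))
    rank_of <- function(m) {
      l <- as.vector(m$labels)
      if (l == "none") Inf else coherence_rank(l)
    }
    expect_lte(rank_of(new), rank_of(base))
  }
})

test_that("classification is a pure function of the masks", {
  set.seed(42)
  masks <- lapply(trw_hierarchy, function(h) array(runif(27) < 0.4,
                                                   c(3, 3, 3)))
  names(masks) <- trw_hierarchy
  m1 <- classify_trw(masks)
  m2 <- classify_trw(masks)
  expect_identical(m1, m2)
  expect_equal(dim(m1$labels), c(3, 3, 3))
  expect_error(classify_trw(list(intact = matrix(TRUE, 2, 2),
                                 backward = matrix(TRUE, 3, 3))),
               "share one grid")
  expect_error(classify_trw(list(whatever = c(TRUE))), "hierarchy")
})

test_that("summaries count labels and violations consistently", {
  masks <- mask_set(list(rep(TRUE, 5),
                         c(FALSE, TRUE, FALSE, TRUE, TRUE),
                         rep(FALSE, 5)))
  map <- classify_trw(masks)
  s <- trw_summary(map)
  expect_equal(sum(s$counts), 3)
  expect_equal(unname(s$counts[["backward"]]), 1)
  expect_equal(unname(s$counts[["none"]]), 1)
  expect_equal(s$n_violation, 1)
  # empty grid
  empty <- classify_trw(stats::setNames(
    lapply(1:5, function(i) logical(0)), trw_hierarchy))
  se <- trw_summary(empty)
  expect_true(all(se$counts == 0))
  expect_equal(se$violation_rate, 0)
})

test_that("scoring against truth reports exact and adjacent accuracy", {
  truth <- array(c("backward", "measure", "phrase", "section",
                   "intact", "none", "none", "phrase"), c(2, 2, 2))
  perfect_masks <- lapply(seq_along(trw_hierarchy), function(i) {
    array(coherence_rank(truth) <= i, dim(truth))
  })
  names(perfect_masks) <- trw_hierarchy
  map <- classify_trw(perfect_masks)
  sc <- score_against_truth(map, truth)
  expect_equal(sc$accuracy, 1)
  expect_equal(sc$adjacent_accuracy, 1)
  expect_true(all(diag(sc$confusion[1:5, 1:5]) ==
                    table(factor(as.vector(truth),
                                 trw_hierarchy))[rownames(sc$confusion)[1:5]]))
  # all-"none" map: accuracy equals the truth fraction of "none"
  none_masks <- lapply(trw_hierarchy, function(h) array(FALSE, dim(truth)))
  names(none_masks) <- trw_hierarchy
  sc0 <- score_against_truth(classify_trw(none_masks), truth)
  expect_equal(sc0$accuracy, mean(truth == "none"))
  expect_error(score_against_truth(map, array("none", c(3, 3, 3))),
               "mismatch")
})
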