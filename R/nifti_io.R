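#' Write a BOLD run as NIfTI-1
#'
#' Stores the 4D array with voxel sizes in `pixdim[1:3]` (mm) and the TR in
#' `pixdim[4]` (s), plus a JSON sidecar recording subject, condition, TR,
#' and processing provenance.
#'
#' @param run a [bold_run()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param sidecar write the JSON sidecar next to the image (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(run, path, sidecar = TRUE) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(run$voxel_size, run$tr)
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path)
  if (sidecar) {
    meta <- list(subject = run$subject, condition = run$condition,
                 tr = run$tr, voxel_size = run$voxel_size,
                 provenance = run$provenance)
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE)
  }
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read a BOLD run from NIfTI-1
#'
#' TR is taken from `pixdim[4]` unless overridden; subject, condition, and
#' provenance are restored from the JSON sidecar when present.
#'
#' @param path NIfTI path.
#' @param tr optional TR override in seconds.
#' @return a [bold_run()].
#' @export
read_bold_nifti <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  data <- array(as.numeric(img), dim = dim(img))
  meta <- list(subject = NA, condition = NA_character_,
               provenance = character())
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    m <- jsonlite::read_json(sc, simplifyVector = TRUE)
    meta[names(m)] <- m
  }
  bold_run(data, tr = if (is.null(tr)) pd[4] else tr,
           voxel_size = pd[1:3], subject = meta$subject,
           condition = meta$condition,
           provenance = as.character(meta$provenance))
}

#' Write a cohort of runs with a manifest
#'
#' One NIfTI per subject and condition (`sub-<i>_cond-<name>.nii.gz`) plus
#' a TSV manifest with columns `subject`, `condition`, `path`.
#'
#' @param runs nested list `runs[[condition]][[subject]]` of [bold_run()].
#' @param dir output directory (created if missing).
#' @return manifest path, invisibly.
#' @export
write_cohort_nifti <- function(runs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (cond in names(runs)) {
    for (s in seq_along(runs[[cond]])) {
      fn <- sprintf("sub-%02d_cond-%s.nii.gz", s, cond)
      write_bold_nifti(runs[[cond]][[s]], file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(subject = s,
                                              condition = cond, path = fn)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort of runs from a manifest
#'
#' @param manifest_path path to a TSV with columns `subject`, `condition`,
#'   `path` (paths relative to the manifest's directory).
#' @param tr optional TR override.
#' @return nested list `runs[[condition]][[subject]]` of [bold_run()].
#' @export
read_cohort_nifti <- function(manifest_path, tr = NULL) {
  man <- read.delim(manifest_path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "condition", "path") %in% names(man)))
  base <- dirname(manifest_path)
  runs <- list()
  for (cond in unique(man$condition)) {
    sub_rows <- man[man$condition == cond, ]
    sub_rows <- sub_rows[order(sub_rows$subject), ]
    runs[[cond]] <- lapply(seq_len(nrow(sub_rows)), function(i) {
      read_bold_nifti(file.path(base, sub_rows$path[i]), tr = tr)
    })
  }
  runs
}

#' Write a TRW map (or truth map) as integer-coded NIfTI + JSON legend
#'
#' @param map a [classify_trw()] result or a [truth_map()].
#' @param path output NIfTI path; the legend is written next to it.
#' @return `path`, invisibly.
#' @export
write_trw_nifti <- function(map, path) {
  labels <- if (inherits(map, "truth_map")) map$labels else map$labels
  lv <- c(trw_hierarchy, "none")
  codes <- array(match(as.vector(labels), lv), dim = dim(labels))
  img <- RNifti::asNifti(codes)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(as.list(stats::setNames(seq_along(lv), lv)),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}
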