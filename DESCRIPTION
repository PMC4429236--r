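Package: trwmap
Title: Temporal Receptive Window Mapping from Inter-Subject Correlation
    of Naturalistic Auditory fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to study how cortical responses to naturalistic auditory
    stimuli depend on hierarchical temporal structure. Builds
    multi-timescale scrambled stimuli (measure-, phrase-, and
    section-level shuffling, time reversal, dynamic-range compression)
    from an audio track and a nested boundary table, simulates subject
    cohorts of BOLD runs with known temporal-receptive-window (TRW)
    structure, preprocesses runs (detrending, high-pass filtering,
    spatial smoothing, initial-volume cropping), computes leave-one-out
    inter-subject correlation (ISC) with phase-randomization
    significance testing and false-discovery-rate control, and derives
    topographic TRW maps and ROI reliability profiles scored against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
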