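#!/usr/bin/env Rscript
# Simulate the subject cohort: a 12x12x12 grid whose ground-truth TRW
# lengthens along x (backward -> measure -> phrase -> section -> intact ->
# none), 15 subjects x 5 conditions, HRF-convolved latents, 172 volumes
# per run. Written as NIfTI with a manifest.

source("analysis/00_config.R")

seg <- read_segmentation_tsv(file.path(cfg$results_dir, "segmentation.tsv"))
truth <- default_truth_map(dim = cfg$grid)
print(truth)

coh <- cohort_spec(n_subjects = cfg$n_subjects, alpha = cfg$alpha,
                   sigma = cfg$sigma, tr = cfg$tr, hrf = TRUE,
                   seed = cfg$seed + 100, silence_s = cfg$silence_s)
runs <- gen_cohort_bold(seg, truth, coh)

manifest <- write_cohort_nifti(runs, cfg$cohort_dir)
write_trw_nifti(truth, file.path(cfg$cohort_dir, "truth.nii.gz"))

n_runs <- sum(lengths(runs))
cat(sprintf("Simulated %d runs (%d subjects x %d conditions), %d volumes each\n",
            n_runs, coh$n_subjects, length(runs),
            dim(runs[[1]][[1]]$data)[4]))
cat("manifest:", manifest, "\n")
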