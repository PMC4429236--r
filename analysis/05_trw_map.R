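#!/usr/bin/env Rscript
# Classify each voxel by the shortest temporal structure that evoked a
# reliable response, and score the recovered map against the simulated
# ground truth.

source("analysis/00_config.R")

masks <- lapply(trw_hierarchy, function(cond) {
  img <- RNifti::readNifti(file.path(cfg$isc_dir,
                                     sprintf("%s_mask.nii.gz", cond)))
  array(as.vector(img) > 0, dim(img))
})
names(masks) <- trw_hierarchy

map <- classify_trw(masks)
write_trw_nifti(map, file.path(cfg$isc_dir, "trw_map.nii.gz"))

s <- trw_summary(map)
print(s$counts)
cat(sprintf("nesting violations: %d (%.1f%%)\n", s$n_violation,
            100 * s$violation_rate))

truth_img <- RNifti::readNifti(file.path(cfg$cohort_dir, "truth.nii.gz"))
lv <- c(trw_hierarchy, "none")
truth_labels <- array(lv[as.vector(truth_img)], dim(truth_img))
sc <- score_against_truth(map, truth_labels)
cat(sprintf("exact-label accuracy: %.3f  adjacent: %.3f\n",
            sc$accuracy, sc$adjacent_accuracy))

write.table(data.frame(label = names(s$counts),
                       n_recovered = as.integer(s$counts),
                       n_truth = as.integer(table(factor(truth_labels,
                                                         lv)))),
            file.path(cfg$results_dir, "trw_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
conf <- as.data.frame.matrix(sc$confusion)
conf <- cbind(truth = rownames(conf), conf)
write.table(conf, file.path(cfg$results_dir, "trw_confusion.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
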