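# Mahalanobis distance matrices between grasps for one subject.
#
# One matrix per modality x feature family (the MANOVA pooled-covariance
# distances the trees are built from), plus the per-modality matrices
# averaged over families that summarize how close any two grasps are.
#
# Writes: results/distances/<modality>_<family>.tsv and
# results/distances/mean_<modality>.tsv.

source("analysis/00_cohort.R")

out <- results_dir("distances")

rec <- generate_recording(demo_config, 1)
trees <- subject_trees(rec, demo_taxonomy_config)

for (mod in c("emg", "glove")) {
  per_family <- lapply(trees[[mod]], function(x) x$distances)
  for (fam in names(per_family)) {
    write_distance_matrix(per_family[[fam]],
                          file.path(out, sprintf("%s_%s.tsv", mod, fam)))
    if (per_family[[fam]]$regularized) {
      cat("note:", mod, fam, "needed ridge regularization of the pooled",
          "covariance (degenerate feature components)\n")
    }
  }
  avg <- average_distances(unname(per_family))
  write_distance_matrix(avg, file.path(out, sprintf("mean_%s.tsv", mod)))
  near <- which(avg$d == min(avg$d[upper.tri(avg$d)]), arr.ind = TRUE)[1, ]
  cat(mod, ": closest grasp pair on average:",
      avg$labels[near[1]], "--", avg$labels[near[2]],
      "at", round(min(avg$d[upper.tri(avg$d)]), 2), "\n")
}
cat("wrote", out, "\n")
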