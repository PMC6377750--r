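# Compare the taxonomies: the edit-distance report (modality taxonomies
# against each other, against their feature supertrees and against the
# general taxonomy; inter- and intra-subject variability), with the
# published 40-subject reference values alongside for audit, plus a
# linkage sensitivity run (average vs single vs complete).
#
# Writes: results/comparison/edit_distance_report.tsv and
# results/comparison/linkage_sensitivity.tsv.

source("analysis/00_cohort.R")
library(data.table)

out <- results_dir("comparison")

recordings <- generate_cohort(demo_config)
bundle <- run_taxonomy(recordings, demo_taxonomy_config)
report <- compare_taxonomies(bundle)
fwrite(report, file.path(out, "edit_distance_report.tsv"), sep = "\t")

cat("TED(emg taxonomy, glove taxonomy) =",
    report$value[report$comparison == "modality_taxonomies"],
    "(published 40-subject reference:",
    report$reference[report$comparison == "modality_taxonomies"], ")\n")
cat("IAV vs MAV EMG feature supertrees:",
    tree_edit_distance(bundle$feature_supertrees$emg$IAV,
                       bundle$feature_supertrees$emg$MAV), "\n")

sens <- list()
for (lk in c("average", "single", "complete")) {
  tc <- taxonomy_config(demo_grasp_set, linkage = lk, k_max = 8L)
  b <- run_taxonomy(recordings, tc)
  sens[[length(sens) + 1L]] <- data.table(
    linkage = lk,
    ted_emg_glove = tree_edit_distance(b$modality_taxonomies$emg,
                                       b$modality_taxonomies$glove),
    rf_general_planted = robinson_foulds(b$general_taxonomy,
                                         demo_config$planted_tree),
    general_taxonomy = as_newick(b$general_taxonomy))
}
sens <- rbindlist(sens)
fwrite(sens, file.path(out, "linkage_sensitivity.tsv"), sep = "\t")
print(sens[, .(linkage, ted_emg_glove, rf_general_planted)])
cat("wrote", out, "\n")
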