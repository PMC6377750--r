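# The full three-level taxonomy construction on the demo cohort:
# subject x modality x family trees -> per-family supertrees across
# subjects -> modality taxonomies -> the general taxonomy.
#
# Writes the complete artifact tree (Newick files, distance matrices and
# the edit-distance report) under results/taxonomy/.

source("analysis/00_cohort.R")

out <- results_dir("taxonomy")

recordings <- generate_cohort(demo_config)
bundle <- run_taxonomy(recordings, demo_taxonomy_config)
write_report(bundle, out)

cat("general taxonomy: ", as_newick(bundle$general_taxonomy), "\n")
for (mod in c("emg", "glove")) {
  cat(mod, "taxonomy:     ", as_newick(bundle$modality_taxonomies[[mod]]), "\n")
}
cat("planted tree:     ", as_newick(demo_config$planted_tree), "\n")
cat("RF(general, planted) =",
    robinson_foulds(bundle$general_taxonomy, demo_config$planted_tree), "\n")
cat("wrote", out, "\n")
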