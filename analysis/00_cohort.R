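# Shared cohort definition for the analysis scripts.
#
# The demo cohort uses eight grasps whose names come from the hand-taxonomy
# literature, ordered so that the balanced planted tree pairs grasps that
# real taxonomies place together: (large diameter, medium wrap) and
# (small diameter, fixed hook) as power grasps, (prismatic pinch, tip
# pinch) and (lateral, extension type) on the precision/side-opposition
# side. Five subjects, six repetitions, 5 s movement / 3 s rest — the
# acquisition protocol at full temporal scale.

library(grasptaxa)

demo_grasp_set <- grasp_set(
  1:8,
  c("large_diameter", "medium_wrap", "small_diameter", "fixed_hook",
    "prismatic_pinch", "tip_pinch", "lateral", "extension_type"))

demo_config <- synth_config(
  n_subjects = 5,
  grasp_set = demo_grasp_set,
  n_repetitions = 6,
  seed = 42)

demo_taxonomy_config <- taxonomy_config(demo_grasp_set, k_max = 8L)

results_dir <- function(...) {
  p <- file.path("results", ...)
  dir.create(p, recursive = TRUE, showWarnings = FALSE)
  p
}
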