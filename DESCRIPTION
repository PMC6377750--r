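Package: grasptaxa
Title: Quantitative Hand-Grasp Taxonomies from Muscular and Kinematic Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds quantitative taxonomies of human hand grasps from
    multi-subject surface electromyography and data-glove recordings.
    Windowed time-domain features (RMS, MAV, IAV, WL and the time-domain
    statistics set) feed one-way MANOVA pooled-covariance Mahalanobis
    distances between grasps; per-subject hierarchical trees are merged
    into modality-specific and general taxonomies by supertrees that
    minimize total subtree-prune-and-regraft distance via maximum
    agreement forests, and taxonomies are compared by tree edit distance
    and Robinson-Foulds distance. Includes a synthetic-cohort generator
    with a planted grasp-similarity tree for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
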