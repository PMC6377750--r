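#' @title The full taxonomy pipeline
#'
#' @description
#' Orchestrates the three-level construction: per subject and modality,
#' one tree per feature family (from the Mahalanobis distance matrix of
#' that family's windowed features); per modality and family, a supertree
#' over all subjects (the subject-independent modality-feature tree); per
#' modality, a taxonomy merging its five feature supertrees; and finally
#' the general taxonomy merging the two modality taxonomies. Every stage
#' is deterministic given the configuration.
#'
#' @name pipeline
NULL

.modalities <- c("emg", "glove")

#' Pipeline run configuration
#'
#' @param grasp_set a [grasp_set()]
#' @param window_ms,overlap_ms feature windowing (defaults 200 / 100 ms)
#' @param zc_threshold,ssc_threshold feature gates (default 0)
#' @param linkage agglomeration linkage (default `"average"`)
#' @param ridge_lambda Mahalanobis ridge coefficient (default 1e-6)
#' @param k_max exact-SPR search bound (default 12)
#' @param max_iter supertree hill-climb rounds (default 25)
#' @param families feature families to run (default all five)
#' @param modalities modalities to run (default emg and glove)
#' @param target_fs synchronization grid, Hz (default 2000)
#' @param filter_powerline apply the 50 Hz Hampel filter to EMG (default TRUE)
#' @return a `taxonomy_config`
#' @export
taxonomy_config <- function(grasp_set,
                            window_ms = 200, overlap_ms = 100,
                            zc_threshold = 0, ssc_threshold = 0,
                            linkage = "average", ridge_lambda = 1e-6,
                            k_max = 12L, max_iter = 25L,
                            families = c("RMS", "MAV", "IAV", "TD", "WL"),
                            modalities = c("emg", "glove"),
                            target_fs = 2000, filter_powerline = TRUE) {
  stopifnot(inherits(grasp_set, "grasp_set"), window_ms > overlap_ms)
  families <- match.arg(families, .feature_families, several.ok = TRUE)
  modalities <- match.arg(modalities, .modalities, several.ok = TRUE)
  structure(list(grasp_set = grasp_set, window_ms = window_ms,
                 overlap_ms = overlap_ms, zc_threshold = zc_threshold,
                 ssc_threshold = ssc_threshold, linkage = linkage,
                 ridge_lambda = ridge_lambda, k_max = as.integer(k_max),
                 max_iter = as.integer(max_iter), families = families,
                 modalities = modalities, target_fs = target_fs,
                 filter_powerline = filter_powerline),
            class = "taxonomy_config")
}

#' Subject trees for one recording
#'
#' Preprocesses one recording (line filtering of the EMG, synchronization,
#' windowing) and builds one tree plus its distance matrix per
#' modality x family.
#'
#' @param recording a `signal_recording`
#' @param config a [taxonomy_config()]
#' @return nested list `[[modality]][[family]]` of
#'   `list(tree, distances)`
#' @export
subject_trees <- function(recording, config) {
  wrap <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      stop("subject ", recording$subject_id, ", ", what, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }
  if (config$filter_powerline) {
    recording$emg <- wrap(
      hampel_powerline_filter(recording$emg, recording$fs_emg), "emg filtering")
  }
  rec <- wrap(synchronize(recording, target_fs = config$target_fs),
              "synchronization")
  out <- list()
  for (mod in config$modalities) {
    ws <- wrap(segment_windows(rec, modality = mod,
                               window_ms = config$window_ms,
                               overlap_ms = config$overlap_ms,
                               grasp_set = config$grasp_set),
               paste(mod, "windowing"))
    out[[mod]] <- list()
    for (fam in config$families) {
      spec <- feature_spec(fam, config$zc_threshold, config$ssc_threshold)
      tab <- wrap(build_feature_table(ws, spec), paste(mod, fam, "features"))
      gd <- wrap(grasp_distances(tab, config$grasp_set,
                                 ridge_lambda = config$ridge_lambda),
                 paste(mod, fam, "distances"))
      tree <- distance_tree(gd, linkage = config$linkage)
      out[[mod]][[fam]] <- list(tree = tree, distances = gd)
    }
  }
  out
}

#' Run the complete taxonomy construction
#'
#' @param recordings list of `signal_recording`s (>= 2 subjects)
#' @param config a [taxonomy_config()] (>= 3 grasps)
#' @return a `taxonomy_bundle`: `subject_trees[[subject]][[modality]][[family]]`,
#'   `feature_supertrees[[modality]][[family]]`,
#'   `modality_taxonomies[[modality]]`, `general_taxonomy`,
#'   `distance_matrices` (per subject, plus per-modality family-averaged),
#'   and the `config`
#' @export
run_taxonomy <- function(recordings, config) {
  stopifnot(inherits(config, "taxonomy_config"))
  if (length(recordings) < 2L) stop("need at least 2 subjects")
  if (length(config$grasp_set$grasp_ids) < 3L) stop("need at least 3 grasps")

  per_subject <- lapply(recordings, subject_trees, config = config)
  names(per_subject) <- vapply(recordings, function(r) r$subject_id, character(1))

  sub_trees <- lapply(per_subject, function(s) {
    lapply(s, function(m) lapply(m, function(x) x$tree))
  })
  dist_mats <- lapply(per_subject, function(s) {
    lapply(s, function(m) lapply(m, function(x) x$distances))
  })

  feature_supertrees <- list()
  for (mod in config$modalities) {
    feature_supertrees[[mod]] <- list()
    for (fam in config$families) {
      inputs <- lapply(sub_trees, function(s) s[[mod]][[fam]])
      feature_supertrees[[mod]][[fam]] <-
        build_supertree(inputs, k_max = config$k_max,
                        max_iter = config$max_iter)$tree
    }
  }
  modality_taxonomies <- list()
  for (mod in config$modalities) {
    modality_taxonomies[[mod]] <-
      build_supertree(unname(feature_supertrees[[mod]]),
                      k_max = config$k_max, max_iter = config$max_iter)$tree
  }
  general_taxonomy <-
    build_supertree(unname(modality_taxonomies),
                    k_max = config$k_max, max_iter = config$max_iter)$tree

  averaged <- lapply(stats::setNames(config$modalities, config$modalities),
                     function(mod) {
    per_fam <- unlist(lapply(dist_mats, function(s) s[[mod]]), recursive = FALSE)
    average_distances(unname(per_fam))
  })

  structure(list(subject_trees = sub_trees,
                 feature_supertrees = feature_supertrees,
                 modality_taxonomies = modality_taxonomies,
                 general_taxonomy = general_taxonomy,
                 distance_matrices = dist_mats,
                 averaged_distances = averaged,
                 config = config),
            class = "taxonomy_bundle")
}

#' @export
print.taxonomy_bundle <- function(x, ...) {
  cat("taxonomy_bundle:", length(x$subject_trees), "subjects,",
      length(x$config$modalities), "modalities,",
      length(x$config$families), "families\n")
  cat(" general taxonomy:", as_newick(x$general_taxonomy), "\n")
  invisible(x)
}

#' Edit-distance comparison report for a bundle
#'
#' Tabulates: the TED between the two modality taxonomies; each modality
#' taxonomy against its feature supertrees; the general taxonomy against
#' each modality taxonomy; inter-subject TED statistics per
#' modality x family; and intra-subject statistics across the family
#' trees of each subject x modality. Where a published reference value
#' exists ([reference_edit_distances()]) it is carried in a `reference`
#' column for audit.
#'
#' @param bundle a `taxonomy_bundle`
#' @param costs an [edit_costs()]
#' @return data.frame with columns `comparison`, `modality`, `family`,
#'   `subject`, `value`, `sd`, `reference`
#' @export
compare_taxonomies <- function(bundle, costs = edit_costs()) {
  stopifnot(inherits(bundle, "taxonomy_bundle"))
  mods <- bundle$config$modalities
  fams <- bundle$config$families
  refs <- reference_edit_distances()
  ref_of <- function(comparison, modality, family) {
    hit <- refs$comparison == comparison &
      refs$modality == modality &
      (if (is.na(family)) is.na(refs$family) else !is.na(refs$family) & refs$family == family)
    if (any(hit)) refs$reference[hit][1L] else NA_real_
  }
  row <- function(comparison, modality, family, subject, value, sd = NA_real_) {
    data.frame(comparison = comparison, modality = modality, family = family,
               subject = subject, value = value, sd = sd,
               reference = ref_of(comparison, modality, family))
  }
  out <- list()
  if (length(mods) == 2L) {
    out[[length(out) + 1L]] <- row(
      "modality_taxonomies", paste(mods, collapse = "_vs_"), NA, NA,
      tree_edit_distance(bundle$modality_taxonomies[[mods[1L]]],
                         bundle$modality_taxonomies[[mods[2L]]], costs))
  }
  for (mod in mods) {
    for (fam in fams) {
      out[[length(out) + 1L]] <- row(
        "modality_vs_feature_supertree", mod, fam, NA,
        tree_edit_distance(bundle$modality_taxonomies[[mod]],
                           bundle$feature_supertrees[[mod]][[fam]], costs))
    }
  }
  for (mod in mods) {
    out[[length(out) + 1L]] <- row(
      "general_vs_modality", mod, NA, NA,
      tree_edit_distance(bundle$general_taxonomy,
                         bundle$modality_taxonomies[[mod]], costs))
  }
  for (mod in mods) {
    for (fam in fams) {
      trees <- lapply(bundle$subject_trees, function(s) s[[mod]][[fam]])
      st <- pairwise_stats(unname(trees), "ted", costs = costs)
      out[[length(out) + 1L]] <- row(
        "inter_subject", mod, fam, NA, st$mean, st$sd)
    }
  }
  for (subj in names(bundle$subject_trees)) {
    for (mod in mods) {
      trees <- bundle$subject_trees[[subj]][[mod]]
      st <- pairwise_stats(unname(trees), "ted", costs = costs)
      out[[length(out) + 1L]] <- row("intra_subject", mod, NA, subj,
                                     st$mean, st$sd)
    }
  }
  do.call(rbind, out)
}

#' Write a bundle's trees, matrices and report to a directory
#'
#' Emits one Newick file per tree (subject trees under `subject_trees/`,
#' feature supertrees, modality taxonomies and the general taxonomy at the
#' top level), the per-subject and family-averaged distance matrices as
#' TSV, and the edit-distance comparison report.
#'
#' @param bundle a `taxonomy_bundle`
#' @param path output directory (created)
#' @param costs an [edit_costs()] for the report
#' @return `path`, invisibly
#' @export
write_report <- function(bundle, path, costs = edit_costs()) {
  stopifnot(inherits(bundle, "taxonomy_bundle"))
  if (length(bundle$subject_trees) == 0L) stop("empty bundle")
  dir.create(file.path(path, "subject_trees"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(path, "distance_matrices"), showWarnings = FALSE)
  for (subj in names(bundle$subject_trees)) {
    for (mod in names(bundle$subject_trees[[subj]])) {
      for (fam in names(bundle$subject_trees[[subj]][[mod]])) {
        write_newick(bundle$subject_trees[[subj]][[mod]][[fam]],
                     file.path(path, "subject_trees",
                               sprintf("%s_%s_%s.nwk", subj, mod, fam)))
        write_distance_matrix(bundle$distance_matrices[[subj]][[mod]][[fam]],
                              file.path(path, "distance_matrices",
                                        sprintf("%s_%s_%s.tsv", subj, mod, fam)))
      }
    }
  }
  for (mod in names(bundle$feature_supertrees)) {
    for (fam in names(bundle$feature_supertrees[[mod]])) {
      write_newick(bundle$feature_supertrees[[mod]][[fam]],
                   file.path(path, sprintf("supertree_%s_%s.nwk", mod, fam)))
    }
    write_newick(bundle$modality_taxonomies[[mod]],
                 file.path(path, sprintf("taxonomy_%s.nwk", mod)))
    write_distance_matrix(bundle$averaged_distances[[mod]],
                          file.path(path, sprintf("mean_distances_%s.tsv", mod)))
  }
  write_newick(bundle$general_taxonomy, file.path(path, "taxonomy_general.nwk"))
  report <- compare_taxonomies(bundle, costs = costs)
  data.table::fwrite(report, file.path(path, "edit_distance_report.tsv"),
                     sep = "\t")
  invisible(path)
}
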