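#' @title Recording and tree input/output
#'
#' @description
#' Recordings are kept in a plain-text directory container: one
#' tab-separated file per array (EMG matrix, glove matrix, per-sample
#' stimulus and repetition labels, optional timestamp vectors), named
#' according to a configurable `field_map` whose defaults follow the
#' Ninapro DB2 variable names. Trees are read and written as Newick.
#'
#' @name io_formats
NULL

#' Default field map for the on-disk recording container
#'
#' Maps logical array names to file stems. Defaults follow Ninapro DB2
#' conventions: the re-labelled movement annotations (`restimulus`,
#' `rerepetition`) are used because their movement boundaries are the
#' community standard for that dataset; the raw `stimulus`/`repetition`
#' variants can be selected by overriding the map.
#'
#' @return named character vector
#' @export
default_field_map <- function() {
  c(emg = "emg", glove = "glove",
    stimulus = "restimulus", repetition = "rerepetition",
    ts_emg = "ts_emg", ts_glove = "ts_glove")
}

#' Define the set of grasps under analysis
#'
#' @param grasp_ids integer stimulus codes to analyze (unique, non-zero)
#' @param grasp_names display names, same length; defaults to `grasp_<id>`
#' @return a `grasp_set` object
#' @export
grasp_set <- function(grasp_ids, grasp_names = NULL) {
  grasp_ids <- as.integer(grasp_ids)
  if (anyDuplicated(grasp_ids)) stop("grasp_ids must be unique")
  if (any(grasp_ids == 0L)) stop("stimulus 0 is rest and cannot be a grasp id")
  if (is.null(grasp_names)) grasp_names <- paste0("grasp_", grasp_ids)
  if (length(grasp_names) != length(grasp_ids)) {
    stop("|grasp_ids| must equal |grasp_names|")
  }
  if (anyDuplicated(grasp_names)) stop("grasp names must be unique")
  for (nm in grasp_names) {
    if (!grepl(.valid_label_re, nm)) stop("invalid grasp name: ", nm)
  }
  structure(list(grasp_ids = grasp_ids, grasp_names = as.character(grasp_names)),
            class = "grasp_set")
}

#' The 20-grasp set of the Ninapro DB2 protocol
#'
#' Display names for the 20 object grasps of exercise B/C of the protocol
#' (large diameter, medium wrap, ... in the order commonly used in the
#' hand-taxonomy literature). The stimulus-id assignment is configuration:
#' by default ids 1..20 are used, which matches analyses that restrict the
#' stimulus stream to the grasping movements and renumber them.
#'
#' @param grasp_ids stimulus ids to pair with the 20 names (default 1:20)
#' @return a `grasp_set` with 20 grasps
#' @export
ninapro_grasp_set <- function(grasp_ids = 1:20) {
  names20 <- c(
    "large_diameter", "small_diameter", "fixed_hook", "index_finger_extension",
    "medium_wrap", "ring", "prismatic_four_fingers", "stick", "writing_tripod",
    "power_sphere", "three_finger_sphere", "precision_sphere", "tripod",
    "prismatic_pinch", "tip_pinch", "quadpod", "lateral", "parallel_extension",
    "extension_type", "power_disk")
  stopifnot(length(grasp_ids) == 20L)
  grasp_set(grasp_ids, names20)
}

#' @export
print.grasp_set <- function(x, ...) {
  cat("grasp_set:", length(x$grasp_ids), "grasps\n")
  invisible(x)
}

#' Assemble and validate a multi-modal recording
#'
#' @param subject_id identifier
#' @param emg numeric matrix, samples x channels (mV)
#' @param glove numeric matrix, samples x sensors (joint-angle proportional)
#' @param stimulus integer per-sample movement label on the EMG grid (0 = rest)
#' @param repetition integer per-sample repetition index on the EMG grid
#' @param fs_emg,fs_glove sampling rates in Hz
#' @param timestamps_emg,timestamps_glove strictly increasing seconds;
#'   synthesized from the sampling rates when omitted
#' @return a validated `signal_recording`
#' @export
signal_recording <- function(subject_id, emg, glove, stimulus, repetition,
                             fs_emg = 2000, fs_glove = 25,
                             timestamps_emg = NULL, timestamps_glove = NULL) {
  emg <- as.matrix(emg); glove <- as.matrix(glove)
  storage.mode(emg) <- "double"; storage.mode(glove) <- "double"
  stimulus <- as.integer(stimulus); repetition <- as.integer(repetition)
  if (is.null(timestamps_emg)) timestamps_emg <- (seq_len(nrow(emg)) - 1) / fs_emg
  if (is.null(timestamps_glove)) timestamps_glove <- (seq_len(nrow(glove)) - 1) / fs_glove
  rec <- structure(list(
    subject_id = subject_id, emg = emg, glove = glove,
    stimulus = stimulus, repetition = repetition,
    timestamps_emg = as.numeric(timestamps_emg),
    timestamps_glove = as.numeric(timestamps_glove),
    fs_emg = fs_emg, fs_glove = fs_glove
  ), class = "signal_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  if (nrow(rec$emg) != length(rec$timestamps_emg)) {
    stop("validation error: emg has ", nrow(rec$emg), " rows but ",
         length(rec$timestamps_emg), " emg timestamps")
  }
  if (nrow(rec$glove) != length(rec$timestamps_glove)) {
    stop("validation error: glove has ", nrow(rec$glove), " rows but ",
         length(rec$timestamps_glove), " glove timestamps")
  }
  if (length(rec$stimulus) != nrow(rec$emg)) {
    stop("validation error: stimulus length (", length(rec$stimulus),
         ") does not match emg sample count (", nrow(rec$emg), ")")
  }
  if (length(rec$repetition) != nrow(rec$emg)) {
    stop("validation error: repetition length (", length(rec$repetition),
         ") does not match emg sample count (", nrow(rec$emg), ")")
  }
  if (is.unsorted(rec$timestamps_emg, strictly = TRUE)) {
    stop("validation error: emg timestamps not strictly increasing")
  }
  if (is.unsorted(rec$timestamps_glove, strictly = TRUE)) {
    stop("validation error: glove timestamps not strictly increasing")
  }
  invisible(rec)
}

#' @export
print.signal_recording <- function(x, ...) {
  cat("signal_recording '", x$subject_id, "': ",
      nrow(x$emg), " emg samples x ", ncol(x$emg), " ch @ ", x$fs_emg, " Hz; ",
      nrow(x$glove), " glove samples x ", ncol(x$glove), " sensors @ ",
      x$fs_glove, " Hz\n", sep = "")
  invisible(x)
}

#' Read a recording from its directory container
#'
#' Expects `<path>/<stem>.tsv` for each mandatory array (emg, glove,
#' stimulus, repetition) and optionally the two timestamp vectors; missing
#' timestamps are synthesized from the stated sampling rates.
#'
#' @param path directory of the container
#' @param field_map named character vector, see [default_field_map()]
#' @param fs_emg,fs_glove sampling rates used when timestamps are absent
#' @param subject_id defaults to the directory name
#' @return a validated `signal_recording`
#' @export
read_recording <- function(path, field_map = default_field_map(),
                           fs_emg = 2000, fs_glove = 25, subject_id = NULL) {
  if (!dir.exists(path)) stop("recording container not found: ", path)
  fm <- default_field_map()
  fm[names(field_map)] <- field_map
  fpath <- function(field) file.path(path, paste0(fm[[field]], ".tsv"))
  need <- function(field) {
    f <- fpath(field)
    if (!file.exists(f)) {
      stop("format error: container is missing mandatory array '", field,
           "' (expected file ", basename(f), ")")
    }
    f
  }
  read_mat <- function(f) {
    as.matrix(data.table::fread(f, header = FALSE, sep = "\t"))
  }
  emg <- read_mat(need("emg"))
  glove <- read_mat(need("glove"))
  stimulus <- as.integer(read_mat(need("stimulus"))[, 1L])
  repetition <- as.integer(read_mat(need("repetition"))[, 1L])
  ts_e <- if (file.exists(fpath("ts_emg"))) as.numeric(read_mat(fpath("ts_emg"))[, 1L])
  ts_g <- if (file.exists(fpath("ts_glove"))) as.numeric(read_mat(fpath("ts_glove"))[, 1L])
  if (is.null(subject_id)) subject_id <- basename(normalizePath(path))
  signal_recording(subject_id, emg, glove, stimulus, repetition,
                   fs_emg = fs_emg, fs_glove = fs_glove,
                   timestamps_emg = ts_e, timestamps_glove = ts_g)
}

#' Write a recording to a directory container
#'
#' Inverse of [read_recording()]; timestamps are always written.
#'
#' @param rec a `signal_recording`
#' @param path target directory (created if needed)
#' @param field_map see [default_field_map()]
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path, field_map = default_field_map()) {
  validate_recording(rec)
  fm <- default_field_map()
  fm[names(field_map)] <- field_map
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, field) {
    data.table::fwrite(data.table::as.data.table(x),
                       file.path(path, paste0(fm[[field]], ".tsv")),
                       sep = "\t", col.names = FALSE)
  }
  wr(rec$emg, "emg"); wr(rec$glove, "glove")
  wr(matrix(rec$stimulus, ncol = 1), "stimulus")
  wr(matrix(rec$repetition, ncol = 1), "repetition")
  wr(matrix(rec$timestamps_emg, ncol = 1), "ts_emg")
  wr(matrix(rec$timestamps_glove, ncol = 1), "ts_glove")
  invisible(path)
}

#' Read a Newick tree
#'
#' Parsing is delegated to ape; a structural pre-check reports the character
#' position of unbalanced parentheses, which ape does not.
#'
#' @param path file containing one Newick tree
#' @return a `grasp_tree`
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt)
}

#' Parse a Newick string into a grasp_tree
#' @param text Newick string (one tree)
#' @return a `grasp_tree`
#' @export
parse_newick <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("Newick parse error: unmatched ')' at position ", i)
    }
  }
  if (depth > 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' (string ends at position ",
         length(chars), ")")
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error: not a valid tree string")
  from_ape_phylo(phy)
}

#' Write a tree as canonical Newick
#' @param tree a `grasp_tree`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "grasp_tree"))
  writeLines(as_newick(tree), path)
  invisible(path)
}
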