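#' @title Tree comparison metrics
#'
#' @description
#' Trees are compared with two metrics. The tree edit distance (TED) is
#' the minimal total cost of node deletions, insertions and label renames
#' transforming one rooted tree into the other; the exact
#' dynamic-programming algorithm operates on ordered trees, so unordered
#' trees are first canonicalized (children sorted by smallest descendant
#' leaf label) — the single convention on which printed TED values hinge.
#' Internal nodes all carry one shared null label, so renames effectively
#' act on leaves. The Robinson-Foulds distance counts clades present in
#' exactly one tree and serves as the planted-tree recovery metric.
#'
#' @name tree_metrics
NULL

#' Edit operation costs
#' @param c_delete,c_insert,c_rename non-negative unit costs (default 1)
#' @return an `edit_costs` object
#' @export
edit_costs <- function(c_delete = 1, c_insert = 1, c_rename = 1) {
  stopifnot(c_delete >= 0, c_insert >= 0, c_rename >= 0)
  structure(list(c_delete = c_delete, c_insert = c_insert,
                 c_rename = c_rename), class = "edit_costs")
}

# flatten a canonical tree into postorder arrays for the DP:
# labels ("" for internal nodes), lml (postorder index of leftmost leaf
# descendant), keyroots
ted_flatten <- function(tree) {
  labels <- character(0)
  lml <- integer(0)
  walk <- function(node) {
    if (is.character(node)) {
      labels[length(labels) + 1L] <<- node
      lml[length(lml) + 1L] <<- length(labels)
      return(length(labels))
    }
    first <- NA_integer_
    for (ch in node) {
      idx <- walk(ch)
      if (is.na(first)) first <- lml[idx]
    }
    labels[length(labels) + 1L] <<- ""
    lml[length(lml) + 1L] <<- first
    length(labels)
  }
  walk(tree$node)
  n <- length(labels)
  keyroots <- which(!duplicated(lml, fromLast = TRUE))
  list(labels = labels, lml = lml, keyroots = sort(keyroots), n = n)
}

#' Tree edit distance between two rooted trees
#'
#' Exact ordered-tree edit distance (Zhang-Shasha dynamic programme) after
#' canonicalization. Distance 0 if and only if the canonical trees are
#' identical (under positive costs).
#'
#' @param t1,t2 `grasp_tree` objects (any arity, labelled leaves)
#' @param costs an [edit_costs()] (defaults: unit costs)
#' @return non-negative number
#' @export
tree_edit_distance <- function(t1, t2, costs = edit_costs()) {
  stopifnot(inherits(t1, "grasp_tree"), inherits(t2, "grasp_tree"))
  A <- ted_flatten(t1); B <- ted_flatten(t2)
  cd <- costs$c_delete; ci <- costs$c_insert; cr <- costs$c_rename
  ren <- function(i, j) if (A$labels[i] == B$labels[j]) 0 else cr

  td <- matrix(0, A$n, B$n)
  for (i in A$keyroots) {
    for (j in B$keyroots) {
      li <- A$lml[i]; lj <- B$lml[j]
      m <- i - li + 2L; n <- j - lj + 2L
      fd <- matrix(0, m, n)
      for (di in 2:m) fd[di, 1L] <- fd[di - 1L, 1L] + cd
      for (dj in 2:n) fd[1L, dj] <- fd[1L, dj - 1L] + ci
      for (di in 2:m) {
        ni <- li + di - 2L            # node index in T1
        for (dj in 2:n) {
          nj <- lj + dj - 2L
          if (A$lml[ni] == li && B$lml[nj] == lj) {
            fd[di, dj] <- min(fd[di - 1L, dj] + cd,
                              fd[di, dj - 1L] + ci,
                              fd[di - 1L, dj - 1L] + ren(ni, nj))
            td[ni, nj] <- fd[di, dj]
          } else {
            fd[di, dj] <- min(fd[di - 1L, dj] + cd,
                              fd[di, dj - 1L] + ci,
                              fd[A$lml[ni] - li + 1L, B$lml[nj] - lj + 1L] +
                                td[ni, nj])
          }
        }
      }
    }
  }
  td[A$n, B$n]
}

#' Robinson-Foulds distance between two rooted trees
#'
#' Number of clades (internal-node leaf sets) present in exactly one of
#' the two trees; 0 iff the unordered topologies agree.
#'
#' @param t1,t2 `grasp_tree` objects on the same leaf set
#' @return even non-negative integer (for binary trees)
#' @export
robinson_foulds <- function(t1, t2) {
  l1 <- sort(tree_leaves(t1), method = "radix")
  l2 <- sort(tree_leaves(t2), method = "radix")
  if (!identical(l1, l2)) {
    stop("leaf-set mismatch: ",
         paste(union(setdiff(l1, l2), setdiff(l2, l1)), collapse = ", "))
  }
  key <- function(tree) {
    vapply(tree_clades(tree), paste, character(1), collapse = "|")
  }
  k1 <- key(t1); k2 <- key(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Mean and standard deviation of a metric over all tree pairs
#'
#' @param trees list of >= 2 `grasp_tree`s
#' @param metric `"ted"` or `"rf"`, or a function of two trees
#' @param ... passed to the metric (e.g. `costs` for TED)
#' @return list with `mean`, `sd`, `n_pairs`, `values`
#' @export
pairwise_stats <- function(trees, metric = c("ted", "rf"), ...) {
  if (length(trees) < 2L) stop("need at least 2 trees")
  fn <- if (is.function(metric)) metric else {
    switch(match.arg(metric),
           ted = function(a, b, ...) tree_edit_distance(a, b, ...),
           rf = function(a, b, ...) robinson_foulds(a, b))
  }
  n <- length(trees)
  vals <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      vals <- c(vals, fn(trees[[i]], trees[[j]], ...))
    }
  }
  list(mean = mean(vals), sd = stats::sd(vals),
       n_pairs = length(vals), values = vals)
}

#' Published reference edit distances for the 40-subject Ninapro DB2 study
#'
#' The edit distances reported for the full 40-subject, 20-grasp analysis
#' of this procedure, included so a run on the real cohort can print its
#' values alongside them for audit. They are reference points, not test
#' expectations: reproducing them exactly depends on conventions the
#' original analysis leaves open (linkage, tie-breaking, the ordered-TED
#' canonicalization, the SPR rearrangement schedule).
#'
#' @return data.frame with columns `comparison`, `modality`, `family`,
#'   `reference`
#' @export
reference_edit_distances <- function() {
  rbind(
    data.frame(comparison = "modality_taxonomies", modality = "emg_vs_glove",
               family = NA_character_, reference = 33),
    data.frame(comparison = "general_vs_modality",
               modality = c("emg", "glove"), family = NA_character_,
               reference = c(29, 42)),
    data.frame(comparison = "modality_vs_feature_supertree",
               modality = "emg",
               family = c("IAV", "MAV", "RMS", "TD", "WL"),
               reference = c(22, 22, 34, 24, 39)),
    data.frame(comparison = "modality_vs_feature_supertree",
               modality = "glove",
               family = c("IAV", "MAV", "RMS", "TD", "WL"),
               reference = c(19, 31, 0, 34, 26))
  )
}
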