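#' @title From distance matrices to rooted trees
#'
#' @description
#' Hierarchical agglomerative (bottom-up) clustering of the grasp distance
#' matrix produces a dendrogram: each grasp starts as a singleton and the
#' two closest clusters are merged until a single tree remains. The
#' dendrogram is then stripped of its heights to give the unordered rooted
#' unweighted tree that the supertree and edit-distance machinery operate
#' on. Ties between equally distant cluster pairs are broken
#' lexicographically (by the smallest leaf label of each cluster, then the
#' second), so the whole map from matrix to tree is deterministic.
#'
#' The agglomeration is written out explicitly rather than delegated to
#' [stats::hclust()] because the tie-break order is part of the contract
#' here; `hclust` is used as an independent cross-check on tie-free inputs
#' in the test suite.
#'
#' @name trees
NULL

#' Agglomerative clustering with deterministic tie-breaking
#'
#' @param gd a `grasp_dist` (or plain symmetric matrix with dimnames)
#' @param linkage `"average"` (UPGMA, default), `"single"` or `"complete"`
#' @return a `dendrogram_merges` object: list of (members_a, members_b,
#'   height) merges in order, plus leaf labels
#' @export
agglomerate <- function(gd, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  d <- if (inherits(gd, "grasp_dist")) gd$d else as.matrix(gd)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("g", seq_len(nrow(d)))
  G <- nrow(d)
  if (G < 2L) stop("need at least 2 items to cluster")

  # active clusters: list of sorted label vectors; nodes: tree fragments
  clusters <- as.list(labels)
  nodes <- as.list(labels)
  sizes <- rep(1L, G)
  D <- d
  merges <- list()

  for (step in seq_len(G - 1L)) {
    n_act <- length(clusters)
    # find minimum distance pair with lexicographic tie-break:
    # order pairs by (smallest member label, then the other cluster's
    # smallest label), taking the pair key as the sorted label pair
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(n_act - 1L)) {
      for (j in (i + 1L):n_act) {
        dij <- D[i, j]
        key <- sort(c(clusters[[i]][1L], clusters[[j]][1L]), method = "radix")
        better <- dij < best_d - 1e-12 ||
          (abs(dij - best_d) <= 1e-12 &&
             (key[1L] < best_key[1L] ||
                (key[1L] == best_key[1L] && key[2L] < best_key[2L])))
        if (is.null(best) || better) {
          best <- c(i, j); best_d <- dij; best_key <- key
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    merges[[step]] <- list(members_a = clusters[[i]],
                           members_b = clusters[[j]],
                           height = D[i, j])
    # linkage update against every other cluster
    keep <- setdiff(seq_len(n_act), c(i, j))
    new_row <- vapply(keep, function(k) {
      switch(linkage,
        average  = (sizes[i] * D[i, k] + sizes[j] * D[j, k]) / (sizes[i] + sizes[j]),
        single   = min(D[i, k], D[j, k]),
        complete = max(D[i, k], D[j, k]))
    }, numeric(1))
    new_cluster <- sort(c(clusters[[i]], clusters[[j]]), method = "radix")
    new_node <- list(nodes[[i]], nodes[[j]])
    new_size <- sizes[i] + sizes[j]

    clusters <- c(clusters[keep], list(new_cluster))
    nodes <- c(nodes[keep], list(new_node))
    sizes <- c(sizes[keep], new_size)
    if (length(keep)) {
      D <- rbind(cbind(D[keep, keep, drop = FALSE], new_row),
                 c(new_row, 0))
    } else {
      D <- matrix(0, 1, 1)
    }
  }
  structure(list(merges = merges, labels = labels, linkage = linkage,
                 root_node = nodes[[1L]]),
            class = "dendrogram_merges")
}

#' @export
print.dendrogram_merges <- function(x, ...) {
  cat("dendrogram:", length(x$labels), "leaves,", length(x$merges),
      "merges (", x$linkage, "linkage )\n")
  invisible(x)
}

#' Merge heights of a dendrogram
#' @param dend a `dendrogram_merges`
#' @return numeric vector of heights, in merge order
#' @export
merge_heights <- function(dend) {
  vapply(dend$merges, function(m) m$height, numeric(1))
}

#' Cophenetic distance matrix of a dendrogram
#'
#' Distance at which two leaves are first joined; under average linkage on
#' an ultrametric input this reproduces the input matrix exactly.
#'
#' @param dend a `dendrogram_merges`
#' @return symmetric matrix with the dendrogram's labels
#' @export
cophenetic_matrix <- function(dend) {
  labs <- dend$labels
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (mg in dend$merges) {
    m[mg$members_a, mg$members_b] <- mg$height
    m[mg$members_b, mg$members_a] <- mg$height
  }
  m
}

#' Convert a dendrogram to an unweighted rooted tree
#'
#' Topology is preserved, merge heights are discarded, children are put in
#' canonical (unordered-tree) order. The result is binary and rooted at
#' the final merge.
#'
#' @param dend a `dendrogram_merges`
#' @return a `grasp_tree`
#' @export
to_phylo <- function(dend) {
  stopifnot(inherits(dend, "dendrogram_merges"))
  grasp_tree(dend$root_node)
}

#' Distance matrix straight to tree
#'
#' Convenience composition of [agglomerate()] and [to_phylo()].
#'
#' @param gd a `grasp_dist`
#' @param linkage linkage method, see [agglomerate()]
#' @return a `grasp_tree`
#' @export
distance_tree <- function(gd, linkage = "average") {
  to_phylo(agglomerate(gd, linkage = linkage))
}
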