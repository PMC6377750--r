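# Independent tree oracles used by the test suite. These deliberately use
# different characterizations than the package implementation:
#  - SPR distance via exhaustive search over agreement PARTITIONS
#    (restriction equality + vertex-disjoint Steiner trees), not the
#    bounded edge-cut search;
#  - tree edit distance via enumeration of valid edit MAPPINGS, not the
#    dynamic programme.

# -- basic generators --------------------------------------------------------

# all rooted binary topologies over a label vector ((2n-3)!! trees),
# by sequential insertion of each new leaf above every node
all_rooted_topologies <- function(labels) {
  trees <- list(labels[1L])
  for (lab in labels[-1L]) {
    nxt <- list()
    for (tr in trees) {
      n_spots <- grasptaxa:::node_count_spots(tr)
      for (s in seq_len(n_spots)) {
        nxt[[length(nxt) + 1L]] <- grasptaxa:::node_attach_at(tr, lab, s)
      }
    }
    trees <- nxt
  }
  lapply(trees, grasp_tree)
}

# random multifurcating leaf-labelled tree with at most max_leaves leaves
rand_multi_tree <- function(n_leaves, labels = LETTERS) {
  roots <- as.list(labels[seq_len(n_leaves)])
  while (length(roots) > 1L) {
    k <- if (length(roots) == 2L) 2L else sample(2:min(3L, length(roots)), 1L)
    pick <- sample.int(length(roots), k)
    merged <- roots[pick]
    roots <- c(roots[-pick], list(merged))
  }
  grasp_tree(roots[[1L]])
}

# -- restriction and Steiner machinery for the SPR oracle --------------------

# restrict a nested node to a leaf subset; NULL if empty; suppress unary
restrict_node <- function(node, keep) {
  if (is.character(node)) {
    if (node %in% keep) return(node) else return(NULL)
  }
  kids <- Filter(Negate(is.null), lapply(node, restrict_node, keep = keep))
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) return(kids[[1L]])
  kids
}

canon_str <- function(node) {
  if (is.null(node)) return("")
  as_newick(grasp_tree(node))
}

# per-node Steiner membership for a leaf block: a node is in the minimal
# connecting subtree iff >= 2 of its incident directions contain block
# members. Returns the set of node ids (path strings).
steiner_nodes <- function(node, block, total_in_block) {
  out <- character(0)
  below <- function(nd, path) {
    if (is.character(nd)) {
      cnt <- as.integer(nd %in% block)
    } else {
      cnt <- 0L
      dirs <- integer(length(nd))
      for (i in seq_along(nd)) {
        dirs[i] <- below(nd[[i]], paste0(path, ".", i))
        cnt <- cnt + dirs[i]
      }
      ndirs <- sum(dirs > 0L) + as.integer(total_in_block - cnt > 0L)
      if (ndirs >= 2L) out[[length(out) + 1L]] <<- path
    }
    if (is.character(nd) && cnt > 0L) {
      # leaf in block: it is always part of its component subtree
      out[[length(out) + 1L]] <<- path
    }
    cnt
  }
  below(node, "r")
  out
}

# enumerate set partitions via restricted growth strings
all_partitions <- function(items) {
  n <- length(items)
  parts <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1L
    if (i > n) {
      blocks <- split(items, assign)
      parts[[length(parts) + 1L]] <<- unname(blocks)
      return(invisible(NULL))
    }
    for (b in seq_len(k + 1L)) rec(c(assign, b), max(k, b))
    invisible(NULL)
  }
  rec(integer(0), 0L)
  parts
}

# exact rooted SPR distance by exhaustive agreement-partition search
oracle_spr_distance <- function(t1, t2) {
  rho <- "zzz.rho"
  n1 <- list(rho, t1$node)
  n2 <- list(rho, t2$node)
  leaves <- c(sort(tree_leaves(t1)), rho)
  best <- Inf
  for (part in all_partitions(leaves)) {
    if (length(part) - 1L >= best) next
    ok <- TRUE
    for (b in part) {
      if (canon_str(restrict_node(n1, b)) != canon_str(restrict_node(n2, b))) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    # vertex-disjointness of the connecting subtrees, in both trees
    for (nd in list(n1, n2)) {
      seen <- character(0)
      for (b in part) {
        sn <- steiner_nodes(nd, b, length(b))
        if (any(sn %in% seen)) { ok <- FALSE; break }
        seen <- c(seen, sn)
      }
      if (!ok) break
    }
    if (ok) best <- min(best, length(part) - 1L)
  }
  best
}

# -- brute-force tree edit distance via valid mappings -----------------------

# flatten to postorder with ancestor relation
ted_nodes <- function(tree) {
  labels <- character(0); parent <- integer(0)
  walk <- function(node, par) {
    if (is.character(node)) {
      labels[length(labels) + 1L] <<- node
      parent[length(parent) + 1L] <<- NA_integer_
      idx <- length(labels)
      if (!is.na(par)) parent[idx] <<- par
      return(idx)
    }
    kids <- integer(0)
    for (ch in node) kids <- c(kids, walk(ch, NA))
    labels[length(labels) + 1L] <<- ""
    idx <- length(labels)
    parent[idx] <<- NA_integer_
    for (k in kids) parent[k] <<- idx
    idx
  }
  walk(tree$node, NA_integer_)
  n <- length(labels)
  anc <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    p <- parent[i]
    while (!is.na(p)) { anc[p, i] <- TRUE; p <- parent[p] }
  }
  list(labels = labels, anc = anc, n = n)
}

oracle_ted <- function(t1, t2, costs = edit_costs()) {
  A <- ted_nodes(t1); B <- ted_nodes(t2)
  best <- Inf
  rec <- function(i, pairs, cost) {
    # bound: even mapping everything else cannot beat best
    if (cost >= best) return(invisible(NULL))
    if (i > A$n) {
      total <- cost + (A$n - nrow(pairs)) * costs$c_delete +
        (B$n - nrow(pairs)) * costs$c_insert
      if (total < best) best <<- total
      return(invisible(NULL))
    }
    # leave node i unmapped
    rec(i + 1L, pairs, cost)
    # or map to any valid j
    for (j in seq_len(B$n)) {
      if (nrow(pairs) > 0L) {
        if (j %in% pairs[, 2L]) next
        valid <- TRUE
        for (r in seq_len(nrow(pairs))) {
          i2 <- pairs[r, 1L]; j2 <- pairs[r, 2L]
          if ((i2 < i) != (j2 < j)) { valid <- FALSE; break }
          if (A$anc[i, i2] != B$anc[j, j2] ||
              A$anc[i2, i] != B$anc[j2, j]) { valid <- FALSE; break }
        }
        if (!valid) next
      }
      ren <- if (A$labels[i] == B$labels[j]) 0 else costs$c_rename
      rec(i + 1L, rbind(pairs, c(i, j)), cost + ren)
    }
    invisible(NULL)
  }
  rec(1L, matrix(integer(0), 0, 2), 0)
  best
}
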