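#' @title Rooted grasp trees
#'
#' @description
#' The unit of the whole analysis is an unordered rooted tree with unweighted
#' edges and uniquely labelled leaves (grasp names). Internally a tree is a
#' nested structure: a leaf is a character scalar, an internal node an
#' unnamed list of child nodes. The class `grasp_tree` wraps the root node.
#' Trees produced by agglomerative clustering are strictly binary; the tree
#' edit distance additionally accepts arbitrary arity.
#'
#' Canonical form: at every internal node, children are sorted by their
#' smallest descendant leaf label. Two trees are equal iff their canonical
#' Newick strings are identical. All deterministic tie-breaking in the
#' package is defined through this ordering.
#'
#' @name grasp_tree
NULL

.valid_label_re <- "^[A-Za-z0-9_.-]+$"

#' Construct a grasp_tree from a nested node structure
#'
#' @param node a character scalar (leaf) or unnamed list of child nodes.
#' @return a `grasp_tree` object in canonical form.
#' @export
grasp_tree <- function(node) {
  validate_node(node)
  labs <- node_leaves(node)
  if (anyDuplicated(labs)) {
    stop("duplicate leaf labels: ", paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  structure(list(node = canonical_node(node)), class = "grasp_tree")
}

validate_node <- function(node) {
  if (is.character(node)) {
    if (length(node) != 1L || is.na(node) || !nzchar(node)) {
      stop("leaf labels must be non-empty character scalars")
    }
    if (!grepl(.valid_label_re, node)) {
      stop("invalid leaf label (use letters, digits, '_', '.', '-'): ", node)
    }
    return(invisible(TRUE))
  }
  if (is.list(node)) {
    if (length(node) < 2L) stop("internal nodes need at least 2 children")
    for (ch in node) validate_node(ch)
    return(invisible(TRUE))
  }
  stop("tree nodes must be character leaves or lists of children")
}

node_leaves <- function(node) {
  if (is.character(node)) return(node)
  unlist(lapply(node, node_leaves), use.names = FALSE)
}

# sort children by smallest descendant leaf label, recursively
canonical_node <- function(node) {
  if (is.character(node)) return(node)
  kids <- lapply(node, canonical_node)
  mins <- vapply(kids, function(k) min(node_leaves(k)), character(1))
  kids[order(mins, method = "radix")]
}

#' Leaf labels of a tree
#' @param tree a `grasp_tree`
#' @return character vector of leaf labels (tree order)
#' @export
tree_leaves <- function(tree) {
  stopifnot(inherits(tree, "grasp_tree"))
  node_leaves(tree$node)
}

#' Number of nodes (leaves + internal) of a tree
#' @param tree a `grasp_tree`
#' @return integer count
#' @export
tree_size <- function(tree) {
  count <- function(node) {
    if (is.character(node)) return(1L)
    1L + sum(vapply(node, count, integer(1)))
  }
  count(tree$node)
}

#' Is the tree strictly binary?
#' @param tree a `grasp_tree`
#' @return logical
#' @export
is_binary_tree <- function(tree) {
  chk <- function(node) {
    if (is.character(node)) return(TRUE)
    length(node) == 2L && all(vapply(node, chk, logical(1)))
  }
  chk(tree$node)
}

node_to_newick <- function(node) {
  if (is.character(node)) return(node)
  paste0("(", paste(vapply(node, node_to_newick, character(1)), collapse = ","), ")")
}

#' Canonical Newick string of a tree
#' @param tree a `grasp_tree`
#' @return a single Newick string (unweighted edges, trailing ';')
#' @export
as_newick <- function(tree) {
  stopifnot(inherits(tree, "grasp_tree"))
  paste0(node_to_newick(tree$node), ";")
}

#' Tree equality under the unordered-tree convention
#' @param t1,t2 `grasp_tree` objects
#' @return logical: identical canonical forms
#' @export
trees_equal <- function(t1, t2) {
  identical(as_newick(t1), as_newick(t2))
}

#' Non-trivial clades of a rooted tree
#'
#' Each internal node (including the root) induces a clade: the set of its
#' descendant leaves. Clades are returned as sorted label vectors; they are
#' the currency of the Robinson-Foulds comparison.
#'
#' @param tree a `grasp_tree`
#' @return list of character vectors
#' @export
tree_clades <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (is.character(node)) return(invisible(NULL))
    out[[length(out) + 1L]] <<- sort(node_leaves(node), method = "radix")
    for (ch in node) walk(ch)
    invisible(NULL)
  }
  walk(tree$node)
  out
}

#' Convert a grasp_tree to an ape "phylo" object
#' @param tree a `grasp_tree`
#' @return an object of class `phylo` (rooted, no branch lengths)
#' @export
as_ape_phylo <- function(tree) {
  ape::read.tree(text = as_newick(tree))
}

#' Convert an ape "phylo" object to a grasp_tree
#' @param phy a rooted `phylo` object
#' @return a `grasp_tree`
#' @export
from_ape_phylo <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  build <- function(v) {
    if (v <= n_tip) return(phy$tip.label[v])
    lapply(kids[[as.character(v)]], build)
  }
  grasp_tree(build(root))
}

#' @export
print.grasp_tree <- function(x, ...) {
  cat("grasp_tree:", length(tree_leaves(x)), "leaves\n")
  cat(" ", as_newick(x), "\n")
  invisible(x)
}

#' @export
format.grasp_tree <- function(x, ...) as_newick(x)

# -- internal: random binary tree over given labels (used by simulations) ----

#' Random rooted binary tree over a label set
#'
#' Grows a tree by sequential random attachment: each new leaf is grafted
#' onto a uniformly chosen edge (or above the root). Used for planted trees
#' and simulation studies.
#'
#' @param labels character vector of leaf labels (>= 2)
#' @return a `grasp_tree`
#' @export
random_binary_tree <- function(labels) {
  stopifnot(length(labels) >= 2L)
  node <- labels[1L]
  for (lab in labels[-1L]) {
    spots <- node_count_spots(node)
    pick <- sample.int(spots, 1L)
    node <- node_attach_at(node, lab, pick)
  }
  grasp_tree(node)
}

# number of attachment spots = number of nodes (edge above each node,
# counting the root position as the edge above the root)
node_count_spots <- function(node) {
  if (is.character(node)) return(1L)
  1L + sum(vapply(node, node_count_spots, integer(1)))
}

# attach `lab` above the `pick`-th node in preorder
node_attach_at <- function(node, lab, pick) {
  res <- attach_rec(node, lab, pick)
  stopifnot(res$done)
  res$node
}

attach_rec <- function(node, lab, pick) {
  if (pick == 1L) return(list(node = list(lab, node), done = TRUE, used = 1L))
  used <- 1L
  if (is.list(node)) {
    for (i in seq_along(node)) {
      r <- attach_rec(node[[i]], lab, pick - used)
      if (r$done) {
        node[[i]] <- r$node
        return(list(node = node, done = TRUE, used = NA_integer_))
      }
      used <- used + r$used
    }
  }
  list(node = node, done = FALSE, used = used)
}

#' Balanced planted tree over a label set
#'
#' Builds the "most balanced" rooted binary tree by recursive halving of the
#' label vector; the default planted similarity structure of the synthetic
#' generator.
#'
#' @param labels character vector (>= 2 labels)
#' @return a `grasp_tree`
#' @export
balanced_tree <- function(labels) {
  build <- function(labs) {
    if (length(labs) == 1L) return(labs)
    h <- ceiling(length(labs) / 2)
    list(build(labs[seq_len(h)]), build(labs[-seq_len(h)]))
  }
  grasp_tree(build(labels))
}
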