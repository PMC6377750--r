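#' @title SPR distances and supertrees via maximum agreement forests
#'
#' @description
#' The rooted subtree-prune-and-regraft (SPR) distance between two binary
#' trees on one leaf set equals the size of their maximum agreement forest
#' (MAF) minus one, once both trees are augmented with an artificial root
#' leaf. The distance is computed exactly by the classic bounded search:
#' iterative deepening over the number of cut edges, with the three-way
#' branching on a cherry of the first tree (cut below either cherry leaf,
#' or cut all subtrees pendant on the path connecting them), which explores
#' all edge-cutting possibilities in O(3^k). Supertrees are built in two
#' phases: the input tree with the smallest total SPR distance to the
#' others seeds a hill climb over the full SPR neighbourhood that accepts
#' the best improving move until none remains.
#'
#' @name supertree
NULL

.ROOT_MARK <- -1L   # artificial root leaf id for the rooted-SPR reduction

# ---- internal integer-leaf tree helpers (nested: int scalar | list(a,b)) ---

ileaves <- function(node) {
  if (!is.list(node)) return(node)
  c(ileaves(node[[1L]]), ileaves(node[[2L]]))
}

gt_to_inode <- function(tree, id_of) {
  conv <- function(node) {
    if (is.character(node)) return(id_of[[node]])
    list(conv(node[[1L]]), conv(node[[2L]]))
  }
  conv(tree$node)
}

# remove leaf `id`; returns NULL if node was exactly that leaf,
# otherwise the node with the leaf removed and its parent suppressed
idrop_leaf <- function(node, id) {
  if (!is.list(node)) {
    if (identical(node, id)) return(NULL)
    return(node)
  }
  a <- idrop_leaf(node[[1L]], id)
  if (is.null(a)) return(node[[2L]])
  if (!identical_node(a, node[[1L]])) return(list(a, node[[2L]]))
  b <- idrop_leaf(node[[2L]], id)
  if (is.null(b)) return(node[[1L]])
  list(node[[1L]], b)
}

identical_node <- function(a, b) identical(a, b)

icontains <- function(node, id) {
  if (!is.list(node)) return(identical(node, id))
  icontains(node[[1L]], id) || icontains(node[[2L]], id)
}

# all cherries (pairs of sibling leaves) of an integer tree
icherries <- function(node) {
  out <- list()
  walk <- function(nd) {
    if (!is.list(nd)) return(invisible(NULL))
    if (!is.list(nd[[1L]]) && !is.list(nd[[2L]])) {
      out[[length(out) + 1L]] <<- c(nd[[1L]], nd[[2L]])
    }
    walk(nd[[1L]]); walk(nd[[2L]])
    invisible(NULL)
  }
  walk(node)
  out
}

# are leaves a and c siblings somewhere in node?
isiblings <- function(node, a, c) {
  if (!is.list(node)) return(FALSE)
  if ((identical(node[[1L]], a) && identical(node[[2L]], c)) ||
      (identical(node[[1L]], c) && identical(node[[2L]], a))) return(TRUE)
  isiblings(node[[1L]], a, c) || isiblings(node[[2L]], a, c)
}

# replace the cherry (a,c) by leaf m
icontract <- function(node, a, c, m) {
  if (!is.list(node)) return(node)
  if ((identical(node[[1L]], a) && identical(node[[2L]], c)) ||
      (identical(node[[1L]], c) && identical(node[[2L]], a))) return(m)
  list(icontract(node[[1L]], a, c, m), icontract(node[[2L]], a, c, m))
}

# collapse the path between leaves a and c inside their smallest common
# subtree: the LCA becomes the cherry (a,c); every subtree pendant on the
# path becomes its own component. Returns list(node, pendants).
istrip_path <- function(node, a, c) {
  if (!is.list(node)) return(list(node = node, pendants = list()))
  in1a <- icontains(node[[1L]], a); in1c <- icontains(node[[1L]], c)
  in2a <- icontains(node[[2L]], a); in2c <- icontains(node[[2L]], c)
  if ((in1a && in1c)) {
    r <- istrip_path(node[[1L]], a, c)
    return(list(node = list(r$node, node[[2L]]), pendants = r$pendants))
  }
  if ((in2a && in2c)) {
    r <- istrip_path(node[[2L]], a, c)
    return(list(node = list(node[[1L]], r$node), pendants = r$pendants))
  }
  if (!((in1a && in2c) || (in1c && in2a))) {
    stop("internal error: path endpoints not under this node")
  }
  chain <- function(sub, x) {
    if (!is.list(sub)) return(list(keep = sub, pendants = list()))
    if (icontains(sub[[1L]], x)) {
      r <- chain(sub[[1L]], x)
      list(keep = r$keep, pendants = c(r$pendants, list(sub[[2L]])))
    } else {
      r <- chain(sub[[2L]], x)
      list(keep = r$keep, pendants = c(r$pendants, list(sub[[1L]])))
    }
  }
  ra <- chain(if (in1a) node[[1L]] else node[[2L]], a)
  rc <- chain(if (in1c) node[[1L]] else node[[2L]], c)
  list(node = list(ra$keep, rc$keep), pendants = c(ra$pendants, rc$pendants))
}

# ---- MAF bounded search -----------------------------------------------------

# simplification: remove finished singleton components, contract shared
# cherries. env$next_id supplies fresh ids; env$groups maps id -> original
# leaf-id set. Returns list(t1, forest, done) or a terminal success flag.
maf_simplify <- function(t1, forest, done, env) {
  repeat {
    if (is.null(t1)) {
      return(list(t1 = NULL, forest = forest, done = done, stop = TRUE))
    }
    # rule: singleton component -> finished, retire its leaf from t1
    single <- which(vapply(forest, function(f) !is.list(f), logical(1)))
    if (length(single)) {
      id <- forest[[single[1L]]]
      done <- c(done, list(id))
      forest <- forest[-single[1L]]
      t1 <- if (!is.list(t1)) NULL else idrop_leaf(t1, id)
      next
    }
    if (!is.list(t1)) {
      # leaf sets of t1 and the forest stay in sync, so a lone t1 leaf
      # always faces a singleton component handled above
      stop("internal error: lone leaf with non-singleton forest")
    }
    # rule: shared cherry -> contract in both
    cherries <- icherries(t1)
    hit <- FALSE
    for (ch in cherries) {
      a <- ch[1L]; c_ <- ch[2L]
      comp <- which(vapply(forest, function(f) isiblings(f, a, c_), logical(1)))
      if (length(comp)) {
        m <- env$next_id
        env$next_id <- env$next_id + 1L
        env$groups[[as.character(m)]] <-
          c(env$groups[[as.character(a)]], env$groups[[as.character(c_)]])
        t1 <- icontract(t1, a, c_, m)
        forest[[comp[1L]]] <- icontract(forest[[comp[1L]]], a, c_, m)
        hit <- TRUE
        break
      }
    }
    if (!hit) break
  }
  list(t1 = t1, forest = forest, done = done, stop = FALSE)
}

maf_search <- function(t1, forest, k, done, env) {
  s <- maf_simplify(t1, forest, done, env)
  if (s$stop) return(list(forest = s$forest, done = s$done))
  if (k <= 0L) return(NULL)
  t1 <- s$t1; forest <- s$forest; done <- s$done
  ch <- icherries(t1)[[1L]]
  a <- ch[1L]; c_ <- ch[2L]
  ia <- which(vapply(forest, icontains, logical(1), id = a))
  ic <- which(vapply(forest, icontains, logical(1), id = c_))

  cut_leaf <- function(idx, id) {
    comp <- forest[[idx]]
    rest <- idrop_leaf(comp, id)
    f2 <- forest
    f2[[idx]] <- rest
    c(f2, list(id))
  }
  # branch 1: cut below a
  r <- maf_search(t1, cut_leaf(ia, a), k - 1L, done, env)
  if (!is.null(r)) return(r)
  # branch 2: cut below c
  r <- maf_search(t1, cut_leaf(ic, c_), k - 1L, done, env)
  if (!is.null(r)) return(r)
  # branch 3: same component -> cut everything pendant on the a..c path
  if (ia == ic) {
    sp <- istrip_path(forest[[ia]], a, c_)
    kb <- length(sp$pendants)
    if (kb >= 1L && kb <= k) {
      f2 <- forest
      f2[[ia]] <- sp$node
      f2 <- c(f2, sp$pendants)
      r <- maf_search(t1, f2, k - kb, done, env)
      if (!is.null(r)) return(r)
    }
  }
  NULL
}

# greedy agreement forest (upper bound): always cut below `a`
greedy_forest_k <- function(t1, forest, env) {
  cuts <- 0L
  done <- list()
  repeat {
    s <- maf_simplify(t1, forest, done, env)
    if (s$stop) return(cuts)
    t1 <- s$t1; forest <- s$forest; done <- s$done
    ch <- icherries(t1)[[1L]]
    ia <- which(vapply(forest, icontains, logical(1), id = ch[1L]))
    comp <- forest[[ia]]
    forest[[ia]] <- idrop_leaf(comp, ch[1L])
    forest <- c(forest, list(ch[1L]))
    cuts <- cuts + 1L
  }
}

#' Rooted SPR distance between two trees
#'
#' Exact for distances up to `k_max` via iterative-deepening maximum
#' agreement forest search; beyond the bound, a greedy agreement forest
#' provides an upper bound flagged `exact = FALSE`.
#'
#' @param t1,t2 binary rooted `grasp_tree`s on the same leaf set
#' @param k_max exact-search bound (default 12)
#' @return an `maf_result`: `k` (the distance, or its flagged upper
#'   bound), `components` (leaf-label sets of the agreement forest) and
#'   `exact`
#' @export
spr_distance <- function(t1, t2, k_max = 12L) {
  stopifnot(inherits(t1, "grasp_tree"), inherits(t2, "grasp_tree"))
  l1 <- sort(tree_leaves(t1), method = "radix")
  l2 <- sort(tree_leaves(t2), method = "radix")
  if (!identical(l1, l2)) {
    stop("leaf-set mismatch: ",
         paste(union(setdiff(l1, l2), setdiff(l2, l1)), collapse = ", "))
  }
  if (!is_binary_tree(t1) || !is_binary_tree(t2)) {
    stop("SPR distance requires binary trees")
  }
  if (trees_equal(t1, t2)) {
    return(structure(list(k = 0L, components = list(l1), exact = TRUE),
                     class = "maf_result"))
  }
  id_of <- as.list(seq_along(l1)); names(id_of) <- l1
  n1 <- list(.ROOT_MARK, gt_to_inode(t1, id_of))      # augment with root leaf
  n2 <- list(.ROOT_MARK, gt_to_inode(t2, id_of))

  make_env <- function() {
    env <- new.env(parent = emptyenv())
    env$next_id <- length(l1) + 1L
    env$groups <- stats::setNames(as.list(c(.ROOT_MARK, seq_along(l1))),
                                  as.character(c(.ROOT_MARK, seq_along(l1))))
    env
  }
  expand <- function(components, done, env) {
    expand_one <- function(ids) {
      orig <- unlist(lapply(ids, function(i) env$groups[[as.character(i)]]))
      labs <- l1[orig[orig != .ROOT_MARK]]
      sort(labs, method = "radix")
    }
    comp_ids <- c(lapply(components, ileaves), done)
    comps <- lapply(comp_ids, expand_one)
    comps[vapply(comps, length, integer(1)) > 0L]   # drop pure-root component
  }
  for (k in seq_len(k_max)) {
    env <- make_env()
    r <- maf_search(n1, list(n2), k, list(), env)
    if (!is.null(r)) {
      comps <- expand(r$forest, r$done, env)
      return(structure(list(k = k, components = comps, exact = TRUE),
                       class = "maf_result"))
    }
  }
  env <- make_env()
  kg <- greedy_forest_k(n1, list(n2), env)
  structure(list(k = kg, components = NULL, exact = FALSE),
            class = "maf_result")
}

#' @export
print.maf_result <- function(x, ...) {
  cat("SPR distance:", x$k, if (!x$exact) "(greedy upper bound)", "\n")
  invisible(x)
}

# ---- SPR neighbourhood and supertree construction ---------------------------

#' All trees one rooted SPR move away
#'
#' Every proper subtree is pruned and regrafted onto every edge of the
#' remaining tree (including above its root). Results are canonicalized
#' and deduplicated; the input tree itself is excluded.
#'
#' @param tree a binary rooted `grasp_tree`
#' @return list of `grasp_tree`s (the SPR neighbourhood)
#' @export
spr_neighbors <- function(tree) {
  stopifnot(is_binary_tree(tree))
  node <- tree$node
  if (is.character(node)) return(list())
  self <- as_newick(tree)
  seen <- new.env(parent = emptyenv())
  out <- list()

  subtrees <- list()
  collect <- function(nd, path) {
    if (length(path) > 0L) subtrees[[length(subtrees) + 1L]] <<- path
    if (is.list(nd)) {
      collect(nd[[1L]], c(path, 1L))
      collect(nd[[2L]], c(path, 2L))
    }
  }
  collect(node, integer(0))

  get_at <- function(nd, path) { for (p in path) nd <- nd[[p]]; nd }
  drop_at <- function(nd, path) {
    # remove subtree at path, suppress its parent
    if (length(path) == 1L) return(nd[[3L - path[1L]]])
    nd[[path[1L]]] <- drop_at(nd[[path[1L]]], path[-1L])
    nd
  }
  attach_positions <- function(nd) {
    pos <- list(integer(0))
    if (is.list(nd)) {
      for (i in 1:2) {
        for (p in attach_positions(nd[[i]])) pos[[length(pos) + 1L]] <- c(i, p)
      }
    }
    pos
  }
  attach_at <- function(nd, path, sub) {
    if (length(path) == 0L) return(list(sub, nd))
    nd[[path[1L]]] <- attach_at(nd[[path[1L]]], path[-1L], sub)
    nd
  }

  for (path in subtrees) {
    sub <- get_at(node, path)
    rest <- drop_at(node, path)
    for (pos in attach_positions(rest)) {
      cand <- grasp_tree(attach_at(rest, pos, sub))
      key <- as_newick(cand)
      if (key == self || !is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <- cand
    }
  }
  out
}

#' Build a supertree minimizing total SPR distance
#'
#' Phase 1 scores every input tree by its total SPR distance to all the
#' others and takes the minimizer (ties: lowest index). Phase 2 hill-climbs
#' over the SPR neighbourhood of the current supertree, accepting the move
#' with the largest reduction in total SPR distance (first such move in
#' canonical enumeration order on ties) until no move improves or
#' `max_iter` rearrangement rounds have run. Pairwise distances are cached
#' on canonical Newick keys, so repeated subject trees cost nothing extra.
#'
#' @param trees list of binary rooted `grasp_tree`s on one shared leaf set
#' @param k_max exact-SPR bound passed to [spr_distance()]
#' @param max_iter maximum hill-climb rounds (default 25)
#' @return a `supertree_result`: `tree`, `total_spr`, `trace` (accepted
#'   moves with their totals), `exact` (no greedy fallback was involved)
#' @export
build_supertree <- function(trees, k_max = 12L, max_iter = 25L) {
  if (length(trees) == 0L) stop("need at least one input tree")
  for (t in trees) stopifnot(inherits(t, "grasp_tree"))
  leafsets <- lapply(trees, function(t) sort(tree_leaves(t), method = "radix"))
  for (ls in leafsets) {
    if (!identical(ls, leafsets[[1L]])) stop("input trees must share one leaf set")
  }
  cache <- new.env(parent = emptyenv())
  all_exact <- TRUE
  dist_to <- function(t, u) {
    key <- paste(as_newick(t), as_newick(u))
    key2 <- paste(as_newick(u), as_newick(t))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    r <- spr_distance(t, u, k_max = k_max)
    if (!r$exact) all_exact <<- FALSE
    cache[[key]] <- r$k; cache[[key2]] <- r$k
    r$k
  }
  total <- function(t) sum(vapply(trees, function(u) dist_to(t, u), numeric(1)))

  totals <- vapply(trees, total, numeric(1))
  best_idx <- which.min(totals)                 # ties: lowest index
  current <- trees[[best_idx]]
  current_total <- totals[best_idx]
  trace <- list(list(phase = 1L, tree = as_newick(current),
                     total_spr = current_total))

  iter <- 0L
  while (current_total > 0L && iter < max_iter) {
    iter <- iter + 1L
    improved <- FALSE
    best_move <- NULL; best_total <- current_total
    for (nb in spr_neighbors(current)) {
      tt <- total(nb)
      if (tt < best_total) {                    # first-best on ties
        best_total <- tt; best_move <- nb
      }
    }
    if (!is.null(best_move)) {
      current <- best_move; current_total <- best_total
      trace[[length(trace) + 1L]] <- list(phase = 2L, tree = as_newick(current),
                                          total_spr = current_total)
      improved <- TRUE
    }
    if (!improved) break
  }
  structure(list(tree = current, total_spr = current_total,
                 trace = trace, exact = all_exact),
            class = "supertree_result")
}

#' @export
print.supertree_result <- function(x, ...) {
  cat("supertree: total SPR =", x$total_spr,
      if (!x$exact) "(contains greedy bounds)", "\n ", as_newick(x$tree), "\n")
  invisible(x)
}
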