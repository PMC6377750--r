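test_that("SPR distance handles identity and leaf-set mismatch", {
  t1 <- parse_newick("(((A,B),C),(D,E));")
  r <- spr_distance(t1, t1)
  expect_equal(r$k, 0L)
  expect_true(r$exact)
  expect_identical(r$components, list(sort(tree_leaves(t1))))

  t2 <- parse_newick("((A,B),(C,F));")
  expect_error(spr_distance(parse_newick("((A,B),C);"), t2), "mismatch")
})

test_that("the SPR neighbourhood matches the exhaustive distance-1 set", {
  set.seed(81)
  labs <- LETTERS[1:5]
  topos <- all_rooted_topologies(labs)
  expect_length(topos, 105L)                       # (2*5-3)!!
  keys <- vapply(topos, as_newick, character(1))
  for (i in sample(seq_along(topos), 3)) {
    t0 <- topos[[i]]
    nb_keys <- sort(vapply(spr_neighbors(t0), as_newick, character(1)))
    one_away <- sort(keys[vapply(topos, function(tt)
      oracle_spr_distance(t0, tt) == 1L, logical(1))])
    expect_identical(nb_keys, one_away)
  }
})

test_that("SPR distance equals the agreement-partition oracle on random pairs", {
  set.seed(91)
  labs <- LETTERS[1:5]
  for (i in 1:15) {
    t1 <- random_binary_tree(sample(labs))
    t2 <- random_binary_tree(sample(labs))
    k_oracle <- oracle_spr_distance(t1, t2)
    r12 <- spr_distance(t1, t2)
    r21 <- spr_distance(t2, t1)
    expect_equal(r12$k, k_oracle)
    expect_equal(r21$k, k_oracle)                  # metric symmetry
    expect_true(r12$exact)
    # forest witness: components partition the leaf set
    expect_setequal(unlist(r12$components), labs)
    expect_equal(r12$k == 0, trees_equal(t1, t2))
  }
})

test_that("trees one move apart have SPR distance exactly 1", {
  set.seed(101)
  for (i in 1:5) {
    t1 <- random_binary_tree(sample(LETTERS[1:6]))
    nbs <- spr_neighbors(t1)
    t2 <- nbs[[sample.int(length(nbs), 1)]]
    expect_equal(spr_distance(t1, t2)$k, 1L)
  }
})

test_that("supertrees reproduce unanimity and majority", {
  t <- parse_newick("(((A,B),C),(D,E));")
  r <- build_supertree(list(t, t, t))
  expect_equal(r$total_spr, 0)
  expect_true(trees_equal(r$tree, t))

  tp <- spr_neighbors(t)[[1]]
  stopifnot(spr_distance(t, tp)$k == 1)
  # two inputs at distance 1: optimum is either input, total 1
  r2 <- build_supertree(list(t, tp))
  expect_equal(r2$total_spr, 1)
  expect_true(trees_equal(r2$tree, t) || trees_equal(r2$tree, tp))
  # majority wins
  r3 <- build_supertree(list(t, t, tp))
  expect_equal(r3$total_spr, 1)
  expect_true(trees_equal(r3$tree, t))

  expect_error(build_supertree(list()), "at least one")
  expect_error(build_supertree(list(t, parse_newick("(A,B);"))), "leaf set")
})

test_that("hill-climbing never does worse than the best input tree", {
  set.seed(111)
  labs <- LETTERS[1:6]
  for (i in 1:3) {
    trees <- lapply(1:4, function(j) random_binary_tree(sample(labs)))
    r <- build_supertree(trees, k_max = 8L)
    best_input <- min(vapply(trees, function(t)
      sum(vapply(trees, function(u) spr_distance(t, u)$k, numeric(1))),
      numeric(1)))
    expect_lte(r$total_spr, best_input)
  }
})

test_that("supertree total equals the exhaustive optimum on 5 leaves", {
  set.seed(121)
  labs <- LETTERS[1:5]
  topos <- all_rooted_topologies(labs)
  for (i in 1:2) {
    trees <- lapply(1:3, function(j) random_binary_tree(sample(labs)))
    r <- build_supertree(trees, k_max = 8L)
    exhaustive <- min(vapply(topos, function(cand)
      sum(vapply(trees, function(u) spr_distance(cand, u)$k, numeric(1))),
      numeric(1)))
    expect_equal(r$total_spr, exhaustive)
  }
})
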