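test_that("edit distance basics follow the cost model", {
  t1 <- parse_newick("((A,B),C);")
  expect_equal(tree_edit_distance(t1, t1), 0)
  # one rename between two-leaf trees
  expect_equal(tree_edit_distance(parse_newick("(A,B);"),
                                  parse_newick("(A,C);")), 1)
  # renaming one leaf to a fresh label costs exactly c_rename
  t2 <- parse_newick("((A,Z),C);")
  expect_equal(tree_edit_distance(t1, t2), 1)
  expect_equal(tree_edit_distance(t1, t2, edit_costs(c_rename = 1.5)), 1.5)
  # an expensive rename is replaced by the cheaper delete + insert
  expect_equal(tree_edit_distance(t1, t2, edit_costs(c_rename = 2.5)), 2)
  # growing a cherry = one insert under unit costs
  t3 <- parse_newick("((A,(B,D)),C);")
  expect_equal(tree_edit_distance(t1, t3), 2)   # insert internal node + leaf
  expect_error(edit_costs(c_delete = -1))
})

test_that("edit distance agrees with the mapping-enumeration oracle", {
  set.seed(131)
  for (i in 1:40) {
    t1 <- rand_multi_tree(sample(2:4, 1))
    t2 <- rand_multi_tree(sample(2:4, 1))
    expect_equal(tree_edit_distance(t1, t2), oracle_ted(t1, t2),
                 info = paste(as_newick(t1), as_newick(t2)))
  }
  # and under asymmetric costs
  costs <- edit_costs(c_delete = 2, c_insert = 1, c_rename = 1.5)
  for (i in 1:10) {
    t1 <- rand_multi_tree(3)
    t2 <- rand_multi_tree(4)
    expect_equal(tree_edit_distance(t1, t2, costs), oracle_ted(t1, t2, costs))
  }
})

test_that("edit distance is a metric on canonical trees", {
  set.seed(141)
  trees <- lapply(1:6, function(i) {
    n <- sample(4:8, 1)
    random_binary_tree(sample(LETTERS[1:n]))
  })
  for (i in seq_along(trees)) {
    expect_equal(tree_edit_distance(trees[[i]], trees[[i]]), 0)
    for (j in seq_along(trees)) {
      dij <- tree_edit_distance(trees[[i]], trees[[j]])
      expect_equal(dij, tree_edit_distance(trees[[j]], trees[[i]]))
      if (i != j) {
        expect_true(dij > 0 || trees_equal(trees[[i]], trees[[j]]))
      }
      for (k in seq_along(trees)) {
        expect_lte(dij,
                   tree_edit_distance(trees[[i]], trees[[k]]) +
                     tree_edit_distance(trees[[k]], trees[[j]]) + 1e-9)
      }
    }
  }
})

test_that("Robinson-Foulds counts asymmetric clades", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("(((A,C),B),D);")
  expect_equal(robinson_foulds(t1, t1), 0L)
  # clade-set symmetric difference computed by hand:
  # t1: {AB, CD, ABCD}; t2: {AC, ABC, ABCD} -> 4
  expect_equal(robinson_foulds(t1, t2), 4L)
  expect_equal(robinson_foulds(t2, t1), 4L)
  expect_error(robinson_foulds(t1, parse_newick("((A,B),(C,E));")), "mismatch")

  # symmetry and evenness on random binary pairs
  set.seed(151)
  for (i in 1:10) {
    a <- random_binary_tree(sample(LETTERS[1:7]))
    b <- random_binary_tree(sample(LETTERS[1:7]))
    rf <- robinson_foulds(a, b)
    expect_equal(rf, robinson_foulds(b, a))
    expect_equal(rf %% 2L, 0L)
  }
})

test_that("pairwise statistics summarize all unordered pairs", {
  t <- parse_newick("((A,B),C);")
  st <- pairwise_stats(list(t, t, t), "ted")
  expect_equal(st$mean, 0)
  expect_equal(st$sd, 0)
  expect_equal(st$n_pairs, 3L)

  # three trees with pairwise TEDs {0, x, x} -> mean 2x/3
  t2 <- parse_newick("((A,C),B);")
  sts <- pairwise_stats(list(t, t, t2), "ted")
  x <- tree_edit_distance(t, t2)
  expect_equal(sts$mean, 2 * x / 3)
  expect_equal(sts$sd, stats::sd(c(0, x, x)))
  # list order is irrelevant for the summary
  sts2 <- pairwise_stats(list(t2, t, t), "ted")
  expect_equal(sort(sts$values), sort(sts2$values))
  expect_error(pairwise_stats(list(t)), "at least 2")
})

test_that("published reference distances are exposed for audit", {
  refs <- reference_edit_distances()
  expect_equal(refs$reference[refs$comparison == "modality_taxonomies"], 33)
  emg <- refs[refs$comparison == "modality_vs_feature_supertree" &
                refs$modality == "emg", ]
  expect_equal(emg$reference[match(c("IAV", "WL"), emg$family)], c(22, 39))
})
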