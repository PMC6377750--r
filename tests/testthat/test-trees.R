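dm <- function(v, labels) {
  m <- matrix(0, length(labels), length(labels), dimnames = list(labels, labels))
  m[lower.tri(m)] <- v
  m <- m + t(m)
  grasp_distance_matrix(m, labels)
}

test_that("UPGMA reproduces the hand-evaluated merge sequence", {
  # d(A,B)=1, d(A,C)=4, d(B,C)=4 -> (A,B)@1 then (AB,C)@4
  g <- dm(c(1, 4, 4), c("A", "B", "C"))
  dend <- agglomerate(g, linkage = "average")
  expect_equal(merge_heights(dend), c(1, 4))
  expect_identical(sort(dend$merges[[1]]$members_a), "A")
  expect_identical(as_newick(to_phylo(dend)), "((A,B),C);")
})

test_that("equal distances are resolved by the lexicographic tie-break", {
  labels <- c("D", "B", "C", "A")
  m <- matrix(1, 4, 4, dimnames = list(labels, labels)); diag(m) <- 0
  d1 <- agglomerate(grasp_distance_matrix(m, labels))
  # first merge must pick the lexicographically smallest pair (A,B)
  expect_setequal(c(d1$merges[[1]]$members_a, d1$merges[[1]]$members_b),
                  c("A", "B"))
  expect_setequal(c(d1$merges[[2]]$members_a, d1$merges[[2]]$members_b),
                  c("A", "B", "C"))
  # deterministic: same result on repeated runs
  d2 <- agglomerate(grasp_distance_matrix(m, labels))
  expect_identical(as_newick(to_phylo(d1)), as_newick(to_phylo(d2)))
  expect_identical(as_newick(to_phylo(d1)), "(((A,B),C),D);")
})

test_that("UPGMA cophenetic distances reproduce ultrametric inputs exactly", {
  # ultrametric matrix built from a known dendrogram
  labels <- c("A", "B", "C", "D")
  u <- matrix(c(0, 2, 6, 6,
                2, 0, 6, 6,
                6, 6, 0, 4,
                6, 6, 4, 0), 4, 4, dimnames = list(labels, labels))
  dend <- agglomerate(grasp_distance_matrix(u, labels), linkage = "average")
  expect_equal(cophenetic_matrix(dend), u, tolerance = 1e-12)
})

test_that("agglomeration agrees with hclust on tie-free matrices", {
  set.seed(71)
  for (i in 1:5) {
    n <- 7
    X <- matrix(rnorm(n * 4), n, 4)
    rownames(X) <- LETTERS[1:n]
    d <- dist(X)
    for (lk in c("average", "single", "complete")) {
      dend <- agglomerate(grasp_distance_matrix(as.matrix(d), LETTERS[1:n]),
                          linkage = lk)
      hc <- stats::hclust(d, method = lk)
      expect_equal(sort(merge_heights(dend)), sort(hc$height),
                   tolerance = 1e-12)
      expect_equal(cophenetic_matrix(dend),
                   as.matrix(stats::cophenetic(hc))[LETTERS[1:n], LETTERS[1:n]],
                   tolerance = 1e-12)
    }
  }
})

test_that("dendrogram-to-tree conversion discards heights and is idempotent", {
  g <- dm(c(1, 4, 4), c("A", "B", "C"))
  tree <- to_phylo(agglomerate(g))
  expect_true(is_binary_tree(tree))
  expect_identical(as_newick(tree), as_newick(grasp_tree(tree$node)))
  # single merge
  g2 <- dm(2, c("A", "B"))
  expect_identical(as_newick(to_phylo(agglomerate(g2))), "(A,B);")
  expect_error(agglomerate(grasp_distance_matrix(matrix(0, 1, 1), "A")),
               "at least 2")
})
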