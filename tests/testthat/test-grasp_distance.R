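test_that("pooled-covariance Mahalanobis matches hand computation in 1-D", {
  tab <- make_feature_table(matrix(c(0, 2, 4, 6), 4, 1),
                            grasp_ids = c(1, 1, 2, 2))
  gd <- grasp_distances(tab, grasp_set(1:2, c("A", "B")))
  # group means 1 and 5, pooled variance ((0-1)^2+(2-1)^2+(4-5)^2+(6-5)^2)/2 = 2
  expect_equal(gd$d["A", "B"], 4 / sqrt(2), tolerance = 1e-9)
  expect_equal(diag(gd$d), c(A = 0, B = 0))
})

test_that("identical groups are at distance zero and scaling is irrelevant", {
  X <- matrix(rnorm(40), 20, 2)
  tab <- make_feature_table(rbind(X, X), grasp_ids = rep(1:2, each = 20))
  gd <- grasp_distances(tab, grasp_set(1:2, c("A", "B")))
  expect_equal(gd$d["A", "B"], 0, tolerance = 1e-9)

  set.seed(21)
  Y <- matrix(rnorm(120), 40, 3)
  g <- rep(1:2, each = 20)
  d1 <- grasp_distances(make_feature_table(Y, g), grasp_set(1:2, c("A", "B")))
  d10 <- grasp_distances(make_feature_table(10 * Y, g), grasp_set(1:2, c("A", "B")))
  expect_equal(d1$d, d10$d, tolerance = 1e-9)
})

test_that("distances are invariant under invertible affine maps", {
  set.seed(31)
  for (rep_i in 1:5) {
    X <- matrix(rnorm(60 * 4), 60, 4)
    g <- rep(1:3, each = 20)
    gs <- grasp_set(1:3, c("A", "B", "C"))
    base <- grasp_distances(make_feature_table(X, g), gs)
    A <- matrix(rnorm(16), 4, 4) + 4 * diag(4)     # well-conditioned
    b <- rnorm(4)
    Xt <- X %*% A + matrix(b, 60, 4, byrow = TRUE)
    tf <- grasp_distances(make_feature_table(Xt, g), gs)
    expect_equal(tf$d, base$d, tolerance = 1e-8)
  }
})

test_that("implementation agrees with a brute-force double-loop oracle", {
  set.seed(41)
  X <- matrix(rnorm(48 * 3), 48, 3)
  g <- rep(1:4, each = 12)
  gs <- grasp_set(1:4, c("A", "B", "C", "D"))
  gd <- grasp_distances(make_feature_table(X, g), gs)

  # oracle: explicit elementwise accumulation of W, direct solve
  N <- nrow(X); G <- 4; p <- ncol(X)
  means <- rowsum(X, g) / 12
  W <- matrix(0, p, p)
  for (i in seq_len(N)) {
    dev <- X[i, ] - means[g[i], ]
    for (a in seq_len(p)) for (b in seq_len(p)) {
      W[a, b] <- W[a, b] + dev[a] * dev[b]
    }
  }
  W <- W / (N - G)
  for (gi in 1:3) for (gj in (gi + 1):4) {
    delta <- means[gi, ] - means[gj, ]
    expect_equal(gd$d[gi, gj],
                 sqrt(drop(t(delta) %*% solve(W) %*% delta)),
                 tolerance = 1e-9)
  }

  # independent route: W from the MANOVA residual cross-products
  fit <- stats::manova(X ~ factor(g))
  W2 <- summary(fit)$SS$Residuals / (N - G)
  expect_equal(W, W2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("window order is irrelevant and errors are informative", {
  set.seed(51)
  X <- matrix(rnorm(30 * 2), 30, 2)
  g <- rep(1:3, each = 10)
  gs <- grasp_set(1:3, c("A", "B", "C"))
  d1 <- grasp_distances(make_feature_table(X, g), gs)
  perm <- sample.int(30)
  d2 <- grasp_distances(make_feature_table(X[perm, ], g[perm]), gs)
  expect_equal(d1$d, d2$d, tolerance = 1e-9)

  expect_error(
    grasp_distances(make_feature_table(X[1:21, ], g[1:21]), gs),
    "fewer than 2 windows")
  Xbad <- X; Xbad[3, 1] <- NA
  expect_error(grasp_distances(make_feature_table(Xbad, g), gs), "finite")
})

test_that("singular pooled covariance triggers recorded regularization", {
  set.seed(61)
  base <- rnorm(30)
  X <- unname(cbind(base, base, rnorm(30)))   # two identical columns
  g <- rep(1:3, each = 10)
  gs <- grasp_set(1:3, c("A", "B", "C"))
  gd <- grasp_distances(make_feature_table(X, g), gs)
  expect_true(gd$regularized)
  expect_true(all(is.finite(gd$d)))

  # fully degenerate features fall back to the identity metric
  cons <- make_feature_table(matrix(rep(c(1, 2, 3), each = 10), 30, 1),
                             grasp_ids = g)
  gdc <- grasp_distances(cons, gs)
  expect_true(gdc$regularized)
  expect_equal(gdc$d["A", "B"], 1)         # Euclidean between means 1 and 2
})
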