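#' @title Mahalanobis distances between grasps
#'
#' @description
#' The similarity between grasps is quantified with the machinery of a
#' one-way MANOVA: windows are grouped by movement, and pairs of group
#' mean vectors are compared by the Mahalanobis distance under the pooled
#' within-group covariance
#' \deqn{W = \frac{1}{N-G}\sum_g \sum_{i \in g} (x_i - m_g)(x_i - m_g)^T,}
#' \deqn{d(g,h) = \sqrt{(m_g - m_h)^T W^{-1} (m_g - m_h)}.}
#' The distance is dimensionless and invariant under invertible affine
#' maps of the feature space, so feature families on different scales
#' yield directly comparable matrices.
#'
#' @name grasp_distance
NULL

#' Construct a grasp distance matrix object
#' @param d symmetric non-negative matrix with zero diagonal
#' @param labels grasp names, in matrix order
#' @param n_per_group optional window counts per grasp
#' @param metadata optional list (subject, modality, family)
#' @param regularized logical: did ridge regularization fire?
#' @return a `grasp_dist` object
#' @export
grasp_distance_matrix <- function(d, labels, n_per_group = NULL,
                                  metadata = list(), regularized = FALSE) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), length(labels) == nrow(d))
  if (!all(is.finite(d))) stop("distances must be finite")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  d <- (d + t(d)) / 2
  dimnames(d) <- list(labels, labels)
  structure(list(d = d, labels = as.character(labels),
                 n_per_group = n_per_group, metadata = metadata,
                 regularized = regularized),
            class = "grasp_dist")
}

#' @export
print.grasp_dist <- function(x, ...) {
  cat("grasp_dist:", length(x$labels), "grasps",
      if (x$regularized) "(ridge-regularized)" else "", "\n")
  invisible(x)
}

#' Mahalanobis distance matrix between grasps
#'
#' Pools the within-group covariance over all windows of all repetitions
#' (never averaging repetitions first, to keep the full within-group
#' degrees of freedom), then evaluates all pairwise Mahalanobis distances
#' between the grasp mean vectors. If the pooled covariance is numerically
#' singular — routine when feature components are constant, e.g. zero
#' crossings of smooth glove trajectories — a ridge
#' \eqn{W + \lambda \,\mathrm{tr}(W)/p \, I} is applied and the event is
#' recorded on the result (`regularized = TRUE`). A covariance that is
#' identically zero falls back to the identity metric (plain Euclidean
#' distances between means).
#'
#' @param table a `feature_table` (one subject, one modality, one family)
#' @param grasp_set a [grasp_set()]; distances are ordered by its names
#' @param ridge_lambda ridge coefficient \eqn{\lambda} (default 1e-6)
#' @return a `grasp_dist` with the G x G matrix and metadata
#' @export
grasp_distances <- function(table, grasp_set, ridge_lambda = 1e-6) {
  stopifnot(inherits(table, "feature_table"), inherits(grasp_set, "grasp_set"))
  X <- feature_matrix(table)
  if (!all(is.finite(X))) stop("non-finite feature values")
  g <- table$grasp_id
  ids <- grasp_set$grasp_ids
  if (length(ids) < 2L) stop("need at least 2 grasps")
  counts <- vapply(ids, function(id) sum(g == id), integer(1))
  if (any(counts < 2L)) {
    stop("grasp(s) with fewer than 2 windows: ",
         paste(grasp_set$grasp_names[counts < 2L], collapse = ", "))
  }
  p <- ncol(X); N <- sum(counts); G <- length(ids)

  means <- matrix(0, G, p, dimnames = list(grasp_set$grasp_names, colnames(X)))
  W <- matrix(0, p, p)
  for (k in seq_len(G)) {
    Xg <- X[g == ids[k], , drop = FALSE]
    means[k, ] <- colMeans(Xg)
    cent <- sweep(Xg, 2L, means[k, ])
    W <- W + crossprod(cent)
  }
  W <- W / (N - G)

  regularized <- FALSE
  tr <- sum(diag(W))
  if (tr == 0) {
    W_use <- diag(p)                       # degenerate: Euclidean fallback
    regularized <- TRUE
  } else {
    W_use <- W
    ok <- is_spd(W_use)
    if (!ok) {
      W_use <- W + ridge_lambda * (tr / p) * diag(p)
      regularized <- TRUE
      if (!is_spd(W_use)) stop("pooled covariance not invertible even after ridge")
    }
  }
  Winv_half <- backsolve(chol(W_use), diag(p))   # W^{-1} = H H^T
  Z <- means %*% Winv_half                       # whitened means
  d <- as.matrix(stats::dist(Z))
  grasp_distance_matrix(
    d, grasp_set$grasp_names, n_per_group = counts,
    metadata = list(subject_id = attr(table, "subject_id"),
                    modality = attr(table, "modality"),
                    family = attr(table, "family")),
    regularized = regularized)
}

# Cholesky-based SPD check with a relative condition guard
is_spd <- function(M) {
  ev <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ev)) return(FALSE)
  dg <- diag(ev)^2
  min(dg) > .Machine$double.eps * 1e3 * max(dg)
}

#' Average several grasp distance matrices
#'
#' Used for the per-modality summary matrices that average the Mahalanobis
#' distances over feature families (reporting only; trees are always built
#' per family).
#'
#' @param dlist list of `grasp_dist` objects on the same labels
#' @return a `grasp_dist` holding the elementwise mean
#' @export
average_distances <- function(dlist) {
  stopifnot(length(dlist) >= 1L)
  labels <- dlist[[1L]]$labels
  for (d in dlist) stopifnot(identical(d$labels, labels))
  m <- Reduce(`+`, lapply(dlist, function(d) d$d)) / length(dlist)
  grasp_distance_matrix(m, labels,
                        metadata = list(averaged_over = length(dlist)))
}

#' Write a grasp distance matrix as TSV (labelled)
#' @param gd a `grasp_dist`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_distance_matrix <- function(gd, path) {
  dt <- data.table::as.data.table(gd$d, keep.rownames = "grasp")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
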