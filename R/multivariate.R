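#' Principal component analysis of samples
#'
#' Samples are the observations and genes the variables (samples appear as
#' points in PC space). By default expression is `log10(x + 1)` transformed
#' first — raw magnitudes would let a handful of highly expressed genes
#' dominate the decomposition — then gene-wise centered; unit-variance
#' scaling is optional. The number of retained components is
#' `min(samples - 1, genes)`.
#'
#' @param m an [expression_matrix()].
#' @param log_transform apply `log10(x + 1)` first (default `TRUE`).
#' @param scale also divide each gene by its standard deviation
#'   (zero-variance genes are dropped first when scaling).
#' @return object of class `pca_result`: list with `scores` (samples x
#'   components), `loadings` (genes x components), `var_explained`
#'   (fractions, non-increasing, summing to 1), `sdev`, `center`, `scale`
#'   and `log_transform`.
#' @export
pca <- function(m, log_transform = TRUE, scale = FALSE) {
  v <- expr_values(m)
  if (ncol(v) < 2) tt_stop("PCA needs at least 2 samples")
  if (log_transform) v <- log10p1(v)
  X <- t(v)                         # samples x genes
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) tt_stop("matrix is constant: no variance to decompose")
  if (scale && any(sds == 0)) {
    tt_warn("dropping %d zero-variance gene(s) before scaling", sum(sds == 0))
    X <- X[, sds > 0, drop = FALSE]
  }
  p <- stats::prcomp(X, center = TRUE, scale. = scale)
  ncomp <- min(nrow(X) - 1L, ncol(X))
  scores <- p$x[, seq_len(ncomp), drop = FALSE]
  loadings <- p$rotation[, seq_len(ncomp), drop = FALSE]
  ev <- p$sdev[seq_len(ncomp)]^2
  structure(list(scores = scores, loadings = loadings,
                 var_explained = ev / sum(p$sdev^2),
                 sdev = p$sdev[seq_len(ncomp)],
                 center = p$center,
                 scale = if (scale) p$scale else FALSE,
                 log_transform = log_transform),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = " "), "\n")
  invisible(x)
}

#' Seeded k-means clustering of samples
#'
#' Lloyd's algorithm with `n_restarts` random initializations (distinct
#' rows as starting centroids), keeping the restart with the lowest
#' within-cluster sum of squares. Fully deterministic given `seed`; ties in
#' nearest-centroid assignment break toward the lowest cluster index; an
#' emptied cluster is re-seeded with the point farthest from its centroid.
#'
#' @param x numeric matrix of observations in rows (e.g. PC scores from
#'   [pca()], or samples of an [expression_matrix()] via `t(expr_values(m))`).
#' @param k number of clusters, `2 <= k <= nrow(x)`.
#' @param seed integer seed for the restarts.
#' @param n_restarts number of seeded restarts (default 25).
#' @return object of class `kmeans_result`: list with `k`, `assignment`
#'   (named integer vector), `centroids`, `wcss` (total within-cluster sum
#'   of squares) and `iterations`.
#' @export
kmeans_cluster <- function(x, k, seed = 1, n_restarts = 25) {
  if (inherits(x, "expression_matrix")) x <- t(expr_values(x))
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is_scalar_number(k) || k != floor(k) || k < 2)
    tt_stop("'k' must be an integer >= 2")
  if (k > n) tt_stop("'k' (%d) exceeds the number of observations (%d)", k, n)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      res <- lloyd_once(x, k, sample.int(n, k))
      if (is.null(best) || res$wcss < best$wcss - 1e-12) best <- res
    }
  })
  names(best$assignment) <- rownames(x)
  structure(c(best, list(k = k, seed = seed, n_restarts = n_restarts)),
            class = "kmeans_result")
}

# one Lloyd run from the given initial rows
lloyd_once <- function(x, k, init_rows, max_iter = 200) {
  centers <- x[init_rows, , drop = FALSE]
  assign_old <- rep(0L, nrow(x))
  for (it in seq_len(max_iter)) {
    d2 <- point_center_dist2(x, centers)
    assignment <- max.col(-d2, ties.method = "first")  # lowest index wins ties
    for (j in seq_len(k)) {
      members <- assignment == j
      if (!any(members)) {
        # re-seed empty cluster with the globally worst-fitted point
        far <- which.max(d2[cbind(seq_len(nrow(x)), assignment)])
        centers[j, ] <- x[far, ]
        assignment[far] <- j
        members <- assignment == j
      }
      centers[j, ] <- colMeans(x[members, , drop = FALSE])
    }
    if (identical(assignment, assign_old)) break
    assign_old <- assignment
  }
  d2 <- point_center_dist2(x, centers)
  wcss <- sum(d2[cbind(seq_len(nrow(x)), assignment)])
  list(assignment = assignment, centroids = centers, wcss = wcss,
       iterations = it)
}

point_center_dist2 <- function(x, centers) {
  # n x k matrix of squared Euclidean distances
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

#' @export
print.kmeans_result <- function(x, ...) {
  cat(sprintf("kmeans_result: k = %d, WCSS = %.6g (%d restarts, seed %d)\n",
              x$k, x$wcss, x$n_restarts, x$seed))
  print(x$assignment)
  invisible(x)
}
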