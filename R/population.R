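## Population pipeline: dimensionality reduction of stimulus time courses,
## k-means clustering, per-cluster mean intensities, a histogram overlap
## distance, and the estimator-comparison statistic.

#' Principal-component weights of stimulus time courses
#'
#' Arranges one stimulus time course per row in a matrix `X`, takes its
#' singular value decomposition \eqn{X = U \Sigma V^t} and returns the first
#' columns of the weight matrix \eqn{XV = U\Sigma}. Following the verbatim
#' construction, rows are not mean-centred by default; set `center = TRUE`
#' for conventional PCA.
#'
#' @param X numeric matrix, one stimulus time course per row.
#' @param n_components number of leading components to keep (default 3).
#' @param center subtract the column means first?
#' @return Matrix of weights (rows = cells) with the singular values in
#'   attribute `"d"` and the rotation in `"v"`.
#' @export
pca_weights <- function(X, n_components = 3L, center = FALSE) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("stimulus matrix must not contain missing entries")
  if (all(X == 0)) stop("degenerate (all-zero) stimulus matrix")
  stopifnot(n_components >= 1L, n_components <= min(dim(X)))
  if (center) X <- sweep(X, 2L, colMeans(X))
  sv <- svd(X)
  W <- X %*% sv$v[, seq_len(n_components), drop = FALSE]
  attr(W, "d") <- sv$d
  attr(W, "v") <- sv$v[, seq_len(n_components), drop = FALSE]
  W
}

#' k-means clustering of component weights
#'
#' Minimises the within-cluster sum of squared distances
#' \eqn{E = \sum_i \sum_{x \in C_i} \|x - \mu_i\|^2} with the best of
#' `n_restarts` random initialisations; reproducible under the given seed.
#'
#' @param weights numeric matrix, one point per row (e.g. [pca_weights()]).
#' @param k number of clusters (`k <=` number of points).
#' @param seed integer seed.
#' @param n_restarts random restarts.
#' @return Object of class `"cluster_result"` with `labels`, `centroids`,
#'   `E` (the minimised error) and `k`.
#' @export
kmeans_cluster <- function(weights, k, seed, n_restarts = 20L) {
  weights <- as.matrix(weights)
  stopifnot(k >= 1L, k <= nrow(weights))
  set.seed(seed)
  if (k == nrow(weights)) {  # singleton clusters; stats::kmeans needs k < n
    return(structure(list(labels = seq_len(k), centroids = weights,
                          E = 0, k = k), class = "cluster_result"))
  }
  km <- stats::kmeans(weights, centers = k, nstart = n_restarts,
                      iter.max = 100L)
  structure(list(labels = km$cluster, centroids = km$centers,
                 E = km$tot.withinss, k = k),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("k-means clustering: k = %d, E = %.4g, sizes = %s\n",
              x$k, x$E, paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Mean intensity per cluster
#'
#' Pointwise arithmetic mean of the member intensity estimates in each
#' cluster. Members may be `spikegp_fit` objects (their `x_star` is used) or
#' [intensity_grid()] objects; all must share one grid. Empty clusters are
#' skipped with a warning.
#'
#' @param posteriors list of fits or intensity grids, one per cell.
#' @param labels integer cluster labels (same length).
#' @return Named list of [intensity_grid()] objects, one per non-empty
#'   cluster.
#' @export
cluster_mean_rate <- function(posteriors, labels) {
  xs <- lapply(posteriors, function(p) {
    if (inherits(p, "spikegp_fit")) p$x_star
    else if (inherits(p, "intensity_grid")) p
    else stop("posteriors must be spikegp_fit or intensity_grid objects")
  })
  stopifnot(length(xs) == length(labels))
  d0 <- xs[[1L]]$delta; n0 <- xs[[1L]]$n
  for (x in xs)
    if (x$n != n0 || abs(x$delta - d0) > 1e-12)
      stop("all intensities must share one grid")
  out <- list()
  for (g in sort(unique(labels))) {
    idx <- which(labels == g)
    if (!length(idx)) { warning("empty cluster ", g, " skipped"); next }
    V <- rowMeans(vapply(xs[idx], `[[`, numeric(n0 + 1L), "values"))
    out[[as.character(g)]] <- intensity_grid(V, d0)
  }
  if (length(out) < length(unique(labels)))
    warning("some clusters were empty and were skipped")
  out
}

#' Histogram overlap distance
#'
#' \eqn{H(R, S) = \sum_i \min(R_i, S_i) / \max(\sum_i R_i, \sum_i S_i)}:
#' symmetric, bounded in `[0, 1]`, and equal to 1 exactly when the two count
#' histograms coincide.
#'
#' @param R,S non-negative count vectors on a shared binning.
#' @return Scalar in `[0, 1]`.
#' @examples
#' histogram_distance(c(2, 0), c(1, 1))  # 0.5
#' @export
histogram_distance <- function(R, S) {
  stopifnot(length(R) == length(S))
  if (any(R < 0) || any(S < 0)) stop("histogram counts must be non-negative")
  tot <- max(sum(R), sum(S))
  if (tot == 0) stop("both histograms are empty")
  sum(pmin(R, S)) / tot
}

#' Compare two estimators' error samples
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test between two samples of
#' normalised L2 errors; the conventional significance threshold is
#' `p < 0.05`. With fully tied samples the normal approximation with tie
#' correction is used and the p-value is 1.
#'
#' @param l2_a,l2_b numeric samples (e.g. per-replicate [l2_error()] values
#'   of two estimators).
#' @return List with `statistic` (rank-sum U), `p_value` and `significant`.
#' @export
compare_estimators <- function(l2_a, l2_b) {
  stopifnot(length(l2_a) >= 1L, length(l2_b) >= 1L)
  wt <- suppressWarnings(stats::wilcox.test(l2_a, l2_b, exact = NULL))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       significant = wt$p.value < 0.05)
}
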