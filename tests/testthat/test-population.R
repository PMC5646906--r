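test_that("pca_weights reproduces the SVD identity", {
  set.seed(31)
  X <- matrix(runif(6 * 50), nrow = 6)
  W <- pca_weights(X, 3)
  sv <- svd(X)
  US <- sv$u %*% diag(sv$d)
  ## XV = U Sigma up to per-column sign
  for (j in 1:3)
    expect_lt(min(max(abs(W[, j] - US[, j])),
                  max(abs(W[, j] + US[, j]))), 1e-10)
  ## rotation orthogonality
  V <- attr(W, "v")
  expect_equal(crossprod(V), diag(3), tolerance = 1e-12)
})

test_that("pca_weights degenerate structures behave as expected", {
  row <- sin(seq(0, 2 * pi, length.out = 40))
  X <- rbind(row, row, row)
  W <- pca_weights(X, 2)
  expect_lt(max(abs(W[1, ] - W[2, ])), 1e-10)   # identical rows, equal weights
  expect_lt(max(abs(W[1, ] - W[3, ])), 1e-10)
  ## rank-1 outer product: second singular value vanishes
  Y <- outer(c(1, 2, 3), row)
  expect_lt(attr(pca_weights(Y, 2), "d")[2] / attr(pca_weights(Y, 2), "d")[1],
            1e-10)
  expect_error(pca_weights(matrix(0, 3, 4)), "degenerate")
})

test_that("kmeans_cluster recovers planted blobs and reports E consistently", {
  set.seed(41)
  blob <- rbind(matrix(rnorm(20 * 2, 0, 0.5), ncol = 2),
                matrix(rnorm(20 * 2, 10, 0.5), ncol = 2))
  planted <- rep(1:2, each = 20)
  for (sd_ in 1:20) {
    cl <- kmeans_cluster(blob, k = 2, seed = sd_)
    agree <- max(mean(cl$labels == planted), mean(cl$labels == 3 - planted))
    expect_equal(agree, 1)
  }
  cl <- kmeans_cluster(blob, k = 2, seed = 1)
  ## E equals independent recomputation from labels and centroids
  E <- sum(vapply(seq_len(nrow(blob)), function(i)
    sum((blob[i, ] - cl$centroids[cl$labels[i], ])^2), numeric(1)))
  expect_equal(cl$E, E, tolerance = 1e-10)
  ## k = number of distinct points -> E = 0
  pts <- matrix(c(0, 0, 5, 5, 9, 1), ncol = 2, byrow = TRUE)
  expect_equal(kmeans_cluster(pts, k = 3, seed = 2)$E, 0)
  ## E never exceeds that of a random relabelling
  set.seed(77)
  lab_r <- sample(cl$labels)
  cent_r <- rbind(colMeans(blob[lab_r == 1, ]), colMeans(blob[lab_r == 2, ]))
  E_r <- sum(vapply(seq_len(nrow(blob)), function(i)
    sum((blob[i, ] - cent_r[lab_r[i], ])^2), numeric(1)))
  expect_lte(cl$E, E_r)
})

test_that("cluster_mean_rate averages member intensities", {
  a <- const_grid(1, 5)
  b <- const_grid(3, 5)
  out <- cluster_mean_rate(list(a, b, b), c(1L, 1L, 2L))
  expect_equal(out[["1"]]$values, rep(2, 51))
  expect_equal(out[["2"]]$values, b$values)
  expect_error(cluster_mean_rate(list(a, const_grid(1, 6)), c(1L, 1L)),
               "share")
})

test_that("histogram_distance algebra on hand-evaluated cases", {
  expect_equal(histogram_distance(c(3, 1, 4), c(3, 1, 4)), 1)
  expect_equal(histogram_distance(c(2, 0), c(0, 2)), 0)
  expect_equal(histogram_distance(c(2, 0), c(1, 1)), 0.5)
  expect_error(histogram_distance(c(0, 0), c(0, 0)), "empty")
  expect_error(histogram_distance(c(1, -1), c(1, 1)), "non-negative")
  ## symmetry and bounds on random inputs
  set.seed(13)
  for (i in 1:50) {
    R <- rpois(8, 4); S <- rpois(8, 4)
    if (sum(R) + sum(S) == 0) next
    h <- histogram_distance(R, S)
    expect_equal(h, histogram_distance(S, R))
    expect_gte(h, 0); expect_lte(h, 1)
  }
})

test_that("surrogates from a cluster mean resemble member histograms", {
  ## synthetic analogue of the spike-count comparison: members share one
  ## generating intensity, so the cluster mean regenerates similar counts
  x <- xdet_grid(16 * pi, 0.1)
  members <- list(x, x, x, x)
  mean_x <- cluster_mean_rate(members, rep(1L, 4))[["1"]]
  mdl <- isi_model("IG", 6)
  memb_counts <- unlist(lapply(1:4, function(i)
    vapply(simulate_ensemble(members[[i]], mdl, "rescaling", 10,
                             seed = 100 + i), length, integer(1))))
  surr_counts <- vapply(simulate_ensemble(mean_x, mdl, "rescaling", 40,
                                          seed = 999), length, integer(1))
  ## shared binning (width 5 spikes) as for a spike-count histogram
  brks <- seq(0, max(memb_counts, surr_counts) + 5, by = 5)
  H <- histogram_distance(
    tabulate(findInterval(memb_counts, brks), length(brks)),
    tabulate(findInterval(surr_counts, brks), length(brks)))
  expect_gt(H, 0.7)
})

test_that("compare_estimators applies the two-sided rank-sum convention", {
  r <- compare_estimators(c(1, 2, 3), c(1, 2, 3))
  expect_gt(r$p_value, 0.99)
  expect_false(r$significant)
  ## fully separated samples: exact two-sided p = 2/choose(8,4) at n = 4
  ## (the minimum attainable p at n = 3 is 0.1, so n = 4 is the smallest
  ## group size that can reach significance)
  r4 <- compare_estimators(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(r4$p_value, 2 / choose(8, 4), tolerance = 1e-12)
  expect_true(r4$significant)
})

test_that("an S5-style generator-by-estimator table assembles cleanly", {
  x <- xdet_grid(8 * pi, 0.1)
  rows <- list()
  for (gen in c("inverse", "bernoulli", "rescaling")) {
    seqs <- suppressWarnings(
      simulate_ensemble(x, isi_model("IG", 5.9), gen, m = 3, seed = 7))
    for (est in c("ks35", "ks10", "ks3", "psth", "psth_auto")) {
      r <- switch(est,
        ks35 = kernel_rate(seqs, 35, n = x$n, delta = 0.1),
        ks10 = kernel_rate(seqs, 10, n = x$n, delta = 0.1),
        ks3 = kernel_rate(seqs, 3, n = x$n, delta = 0.1),
        psth = psth_rate(seqs, 2, n = x$n, delta = 0.1),
        psth_auto = psth_rate(seqs, as.numeric(optimal_bin_width(seqs)),
                              n = x$n, delta = 0.1))
      rows[[length(rows) + 1L]] <- data.frame(
        generator = gen, estimator = est, l2 = l2_error(r, x))
    }
  }
  tab <- do.call(rbind, rows)
  expect_equal(nrow(tab), 15L)
  expect_true(all(is.finite(tab$l2)))
})
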