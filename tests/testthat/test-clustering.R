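test_that("PCA projection is exact on intrinsically 2-D data", {
  set.seed(41)
  latent <- matrix(rnorm(30 * 2), 30, 2)          # samples x 2
  basis <- qr.Q(qr(matrix(rnorm(5 * 2), 5, 2)))   # orthonormal embedding
  profiles <- t(latent %*% t(basis) + 1)          # features x samples
  rownames(profiles) <- paste0("f", 1:5)
  colnames(profiles) <- paste0("S", 1:30)
  scores <- pca_project(profiles, 2)
  expect_equal(as.numeric(dist(scores)), as.numeric(dist(latent)),
               tolerance = 1e-10)
  # residual variance beyond the first two components is nil
  ev <- attr(scores, "eigenvalues")
  expect_lt(sum(ev[-(1:2)]), 1e-20)
})

test_that("PCA matches a brute-force eigendecomposition of the covariance", {
  set.seed(42)
  profiles <- matrix(rnorm(12), 3, 4,
                     dimnames = list(paste0("f", 1:3), paste0("S", 1:4)))
  scores <- pca_project(profiles, 2)
  x <- scale(t(profiles), scale = FALSE)
  ed <- eigen(cov(x))
  oracle <- x %*% ed$vectors[, 1:2]
  for (k in 1:2) {  # apply the same sign convention to the oracle
    v <- ed$vectors[, k]
    if (v[which.max(abs(v))] < 0) oracle[, k] <- -oracle[, k]
  }
  expect_equal(unname(scores[, 1:2]), unname(oracle), tolerance = 1e-10)
  expect_equal(sum(attr(scores, "eigenvalues")), sum(diag(cov(x))),
               tolerance = 1e-12)
})

test_that("PCA sign convention and input validation hold", {
  set.seed(43)
  profiles <- matrix(rnorm(40), 4, 10,
                     dimnames = list(paste0("f", 1:4), paste0("S", 1:10)))
  scores <- pca_project(profiles, 2)
  rot <- attr(scores, "rotation")
  for (k in 1:2) expect_gt(rot[which.max(abs(rot[, k])), k], 0)
  constant <- rbind(profiles[1, , drop = FALSE] * 0 + 3)
  expect_error(pca_project(rbind(constant, constant), 2), "non-constant")
})

test_that("knee detection reproduces the hand-worked Kneedle example", {
  res <- select_k_knee(1:6, c(100, 50, 10, 9, 8, 7))
  expect_identical(res$selected_k, 3L)
  # exactly linear decay has no curvature, hence no knee
  expect_true(is.na(select_k_knee(1:5, seq(100, 20, by = -20))$selected_k))
  expect_error(select_k_knee(1:4, c(10, 12, 8, 7)), "non-increasing")
  expect_error(select_k_knee(1:2, c(3, 1)), ">= 3 points")
})

test_that("knee selection recovers the planted number of subgroups", {
  cohort <- simulate_cohort(cohort_config(n_samples = 120, n_genes = 400,
                                          n_cell_types = 6, genes_per_set = 25,
                                          noise_sd = 0, depth_sd = 0, seed = 44))
  scores <- score_cell_types(log_transform(cohort$expression),
                             signature_gene_sets(cohort$signatures))
  pcs <- pca_project(zscore_matrix(scores), 2)
  curve <- compute_inertia_curve(pcs, 1:10, seed = 44)
  expect_true(all(diff(curve$inertia) <= 0))
  expect_identical(select_k_knee(curve$k, curve$inertia)$selected_k, 3L)
})

test_that("k-means finds the exhaustive-search optimum in one dimension", {
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1,
              dimnames = list(paste0("S", 1:6), NULL))
  fit <- kmeans_cluster(x, 2, seed = 1)
  # oracle: best of all 2-partitions by within-cluster sum of squares
  best <- Inf
  for (mask in 1:(2^6 - 2)) {
    part <- as.logical(bitwAnd(mask, 2^(0:5)))
    if (!any(part) || all(part)) next
    ss <- sum((x[part] - mean(x[part]))^2) + sum((x[!part] - mean(x[!part]))^2)
    best <- min(best, ss)
  }
  expect_equal(fit$tot_withinss, best)
  expect_equal(fit$tot_withinss, 4)
  expect_identical(unname(table(fit$labels[1:3]))[1], 3L)  # {0,1,2} together
})

test_that("k-means is deterministic, separable, and keeps the best restart", {
  set.seed(45)
  clouds <- rbind(matrix(rnorm(40, 0, 0.1), 20),
                  matrix(rnorm(40, 50, 0.1), 20))
  rownames(clouds) <- paste0("S", 1:40)
  a <- kmeans_cluster(clouds, 2, seed = 42)
  b <- kmeans_cluster(clouds, 2, seed = 42)
  expect_identical(a$labels, b$labels)
  expect_identical(length(unique(a$labels[1:20])), 1L)
  expect_identical(length(unique(a$labels[21:40])), 1L)
  expect_false(a$labels[1] == a$labels[21])
  expect_lte(a$tot_withinss, min(a$restart_withinss))
  expect_true(all(a$sizes > 0))  # no empty clusters
  expect_identical(names(a$sizes), c("sub0", "sub1"))
  expect_true(all(diff(a$sizes) <= 0))  # decreasing-size label order
  expect_error(kmeans_cluster(clouds, 41, seed = 1), "exceeds")
})

test_that("small clusters are discarded and survivors renumbered", {
  set.seed(46)
  sizes <- c(164, 75, 264, 4)
  centers <- c(0, 20, 40, 60)
  x <- matrix(unlist(mapply(function(n, c) rnorm(n, c, 0.5), sizes, centers)),
              ncol = 1)
  rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  fit <- kmeans_cluster(x, 4, seed = 2)
  expect_identical(unname(fit$sizes), c(264L, 164L, 75L, 4L))
  kept <- filter_small_clusters(fit, 5)
  expect_identical(kept$k, 3L)
  expect_identical(unname(kept$sizes), c(264L, 164L, 75L))
  expect_identical(kept$n_discarded, 4L)
  expect_identical(levels(kept$labels), c("sub0", "sub1", "sub2", "discarded"))
  # no cluster below the threshold: assignment unchanged
  expect_identical(filter_small_clusters(fit, 3), fit)
  # every cluster below the threshold: everything discarded, with a warning
  expect_warning(none <- filter_small_clusters(fit, 1000), "every sample")
  expect_identical(none$k, 0L)
  expect_identical(none$n_discarded, nrow(x))
})

test_that("adjusted Rand index agrees with an independent implementation", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  skip_if_not_installed("mclust")
  set.seed(47)
  for (i in 1:20) {
    a <- sample(3, 40, replace = TRUE)
    b <- sample(4, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
})
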