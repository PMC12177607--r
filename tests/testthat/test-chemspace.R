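test_that("cleaning drops non-finite and constant columns only", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(1, NA, 3, 4), c = c(5, 5, 5, 5),
             d = c(0, 1, 0, 2))
  dm <- descriptor_matrix(X)
  expect_message(out <- clean_descriptors(dm), "dropped 2")
  expect_equal(colnames(out$values), c("a", "d"))
  clean <- descriptor_matrix(X[, c("a", "d")])
  expect_identical(clean_descriptors(clean)$values, clean$values)
  allbad <- descriptor_matrix(X[, c("b", "c")])
  expect_error(clean_descriptors(allbad), "all descriptor columns")
})

test_that("correlation filter applies keep-first policy at the threshold", {
  set.seed(2)
  a <- rnorm(200)
  # construct b with cor(a, b) exactly targeted via orthogonal residual
  mk_cor <- function(a, rho) {
    z <- rnorm(length(a))
    z <- residuals(lm(z ~ a))
    z <- z / sd(z)
    rho * scale(a)[, 1] + sqrt(1 - rho^2) * z
  }
  b96 <- mk_cor(a, 0.96)
  b94 <- mk_cor(a, 0.94)
  expect_equal(cor(a, b96), 0.96, tolerance = 1e-6)
  dm <- descriptor_matrix(cbind(a = a, double_a = 2 * a, b96 = b96,
                                b94 = b94))
  out <- correlation_filter(dm, threshold = 0.95)
  expect_equal(out$dropped, c("double_a", "b96"))
  expect_equal(colnames(out$dm$values), c("a", "b94"))
  # threshold above 1 keeps everything
  out2 <- correlation_filter(dm, threshold = 1.0000001)
  expect_equal(length(out2$dropped), 0)
})

test_that("PCA standardises, orders components and reconstructs at full rank", {
  set.seed(3)
  x <- rnorm(300)
  near_line <- cbind(a = x, b = 2 * x + rnorm(300, sd = 1e-4))
  p1 <- pca_descriptors(descriptor_matrix(near_line), m = 1)
  expect_gte(p1$explained[1], 0.999)

  iso <- matrix(rnorm(10000), 5000, 2)
  p2 <- pca_descriptors(descriptor_matrix(iso), m = 2)
  expect_lt(max(abs(p2$explained - 0.5)), 0.03)

  # full-rank scores reproduce the centred/scaled data
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  dm <- descriptor_matrix(X)
  p3 <- pca_descriptors(dm, m = 3)
  recon <- p3$scores %*% t(p3$loadings)
  expect_equal(recon, scale(X), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(crossprod(p3$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca_descriptors(dm, m = 4), "rank")
})

test_that("k-means finds the optimal 2-partition on small instances", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  km <- kmeans_cluster(X, 2, seed = 1)
  expect_equal(sort(as.vector(km$centroids)), c(0.5, 10.5))
  expect_equal(km$wcss, 1.0)
  expect_equal(km$wcss, exhaustive_wcss_k2(X))

  set.seed(8)
  for (rep in 1:6) {
    n <- sample(6:10, 1)
    Y <- matrix(rnorm(2 * n), n, 2)
    km2 <- kmeans_cluster(Y, 2, seed = rep, n_init = 20)
    expect_equal(km2$wcss, exhaustive_wcss_k2(Y), tolerance = 1e-8)
  }
})

test_that("k-means invariants: labels, centroid means, WCSS identity", {
  gm <- gen_mixture(seed = 5)
  km <- kmeans_cluster(gm$dm$values, 5, seed = 2)
  expect_true(all(km$labels %in% 1:5))
  for (j in 1:5) {
    expect_equal(km$centroids[j, ],
                 colMeans(gm$dm$values[km$labels == j, , drop = FALSE]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_equal(km$wcss, wcss_objective(gm$dm$values, km$labels, km$centroids))
  # translation invariance
  km2 <- kmeans_cluster(gm$dm$values + 100, 5, seed = 2)
  expect_equal(km2$wcss, km$wcss, tolerance = 1e-6)
  expect_equal(km$wcss, kmeans_cluster(gm$dm$values, 5, seed = 2)$wcss)
  expect_equal(kmeans_cluster(gm$dm$values, nrow(gm$dm$values),
                              seed = 1, n_init = 1)$wcss, 0, tolerance = 1e-9)
  expect_error(kmeans_cluster(gm$dm$values, 0), "k must")
  expect_error(kmeans_cluster(gm$dm$values, 1000), "k must")
})

test_that("quality indices match the 1-D hand example", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  km <- kmeans_cluster(X, 2, seed = 1)
  cq <- cluster_quality(X, km)
  expect_equal(cq$wcss, 1.0)
  expect_equal(cq$sil_points[1], (10.5 - 1) / 10.5, tolerance = 1e-6)
  expect_equal(cq$davies_bouldin, 0.1, tolerance = 1e-6)
  expect_equal(cq$calinski_harabasz, 200, tolerance = 1e-6)
  # information criteria: p = k*m + 1 = 3, n = 4
  expect_equal(cq$p, 3)
  expect_equal(cq$aic - cq$bic, 3 * (2 - log(4)), tolerance = 1e-9)
})

test_that("BIC - AIC = p (ln n - 2) exactly for every k", {
  gm <- gen_mixture(seed = 6)
  n <- nrow(gm$dm$values)
  for (k in 2:6) {
    km <- kmeans_cluster(gm$dm$values, k, seed = k)
    cq <- cluster_quality(gm$dm$values, km)
    expect_equal(cq$bic - cq$aic, cq$p * (log(n) - 2), tolerance = 1e-10)
  }
})

test_that("silhouette agrees with the reference implementation", {
  skip_if_not_installed("cluster")
  set.seed(10)
  for (rep in 1:4) {
    X <- matrix(rnorm(80), 40, 2)
    km <- kmeans_cluster(X, 3, seed = rep)
    cq <- cluster_quality(X, km)
    ref <- cluster::silhouette(km$labels, stats::dist(X))
    expect_equal(cq$silhouette, mean(ref[, "sil_width"]), tolerance = 1e-6)
  }
})

test_that("DB and CH agree with independent brute-force formulations", {
  db_brute <- function(X, labels, centroids) {
    k <- nrow(centroids)
    sig <- sapply(1:k, function(i)
      mean(sqrt(colSums((t(X[labels == i, , drop = FALSE]) - centroids[i, ])^2))))
    tot <- 0
    for (i in 1:k) {
      best <- -Inf
      for (j in 1:k) if (j != i) {
        d <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
        best <- max(best, (sig[i] + sig[j]) / d)
      }
      tot <- tot + best
    }
    tot / k
  }
  ch_brute <- function(X, labels, centroids) {
    n <- nrow(X); k <- nrow(centroids)
    g <- colMeans(X)
    trB <- sum(sapply(1:k, function(j)
      sum(labels == j) * sum((centroids[j, ] - g)^2)))
    trW <- sum(sapply(1:n, function(i) sum((X[i, ] - centroids[labels[i], ])^2)))
    (trB / trW) * (n - k) / (k - 1)
  }
  set.seed(14)
  for (rep in 1:4) {
    X <- matrix(rnorm(100), 50, 2)
    km <- kmeans_cluster(X, 4, seed = rep)
    cq <- cluster_quality(X, km)
    expect_equal(cq$davies_bouldin, db_brute(X, km$labels, km$centroids),
                 tolerance = 1e-6)
    expect_equal(cq$calinski_harabasz, ch_brute(X, km$labels, km$centroids),
                 tolerance = 1e-6)
  }
})

test_that("singleton clusters score silhouette 0 and are flagged", {
  X <- rbind(c(0, 0), c(0.5, 0), c(100, 100))
  km <- kmeans_cluster(X, 2, seed = 1)
  cq <- cluster_quality(X, km)
  expect_true(cq$has_singleton)
  expect_equal(cq$sil_points[which(tabulate(km$labels)[km$labels] == 1)], 0)
})

test_that("select_k recovers the planted component count", {
  gm <- gen_mixture(seed = 20)
  out <- select_k(gm$dm$values, k_range = 2:10, seed = 30)
  expect_equal(out$k, 5)
  expect_false(out$weak_structure)
  expect_equal(nrow(out$table), 9)
  # determinism
  out2 <- select_k(gm$dm$values, k_range = 2:10, seed = 30)
  expect_identical(out$table, out2$table)
})

test_that("a single blob raises the weak-structure diagnostic", {
  gm <- gen_mixture(k_true = 1, n_per_cluster = 120, seed = 9)
  out <- select_k(gm$dm$values, k_range = 2:6, seed = 3)
  expect_true(out$weak_structure)   # best silhouette stays in the weak band
  expect_true(all(out$table$silhouette < 0.5))
  expect_error(select_k(gm$dm$values, k_range = integer(0)), "empty")
  expect_error(select_k(gm$dm$values, k_range = 1:3), "k_range")
})

test_that("centroid distances follow the Euclidean formula", {
  X <- rbind(c(0, 0), c(3, 4), c(10, 10), c(10, 10))
  km <- kmeans_cluster(X, 2, seed = 1)
  d <- centroid_distances(X, km)
  expect_equal(d[3], 0)
  expect_equal(d[4], 0)
  # brute force on random data
  set.seed(17)
  Y <- matrix(rnorm(60), 30, 2)
  km2 <- kmeans_cluster(Y, 3, seed = 2)
  d2 <- centroid_distances(Y, km2)
  ref <- vapply(1:30, function(i)
    sqrt(sum((Y[i, ] - km2$centroids[km2$labels[i], ])^2)), numeric(1))
  expect_equal(d2, ref, tolerance = 1e-12)
})

test_that("representative selection takes the nearest molecules per cluster", {
  gm <- gen_mixture(seed = 31)
  km <- kmeans_cluster(gm$dm$values, 5, seed = 4)
  d <- centroid_distances(gm$dm$values, km)
  reps <- select_representatives(km, d, m_per_cluster = 4, ids = gm$dm$ids)
  expect_equal(reps$total, 20)
  for (pc in reps$per_cluster) {
    expect_true(all(diff(pc$distance) >= 0))
    expect_true(all(km$labels[pc$index] == pc$cluster[1]))
    # nothing unselected in the cluster is closer than the selected worst
    others <- setdiff(which(km$labels == pc$cluster[1]), pc$index)
    if (length(others) > 0) expect_gte(min(d[others]), max(pc$distance))
  }
  # truncation: cluster smaller than m_per_cluster
  X <- rbind(c(0, 0), c(1, 0), c(50, 50))
  km2 <- kmeans_cluster(X, 2, seed = 1)
  d2 <- centroid_distances(X, km2)
  reps2 <- select_representatives(km2, d2, m_per_cluster = 4)
  expect_equal(reps2$total, 3)
  expect_equal(length(reps2$truncated), 2)
  expect_error(select_representatives(km2, d2, m_per_cluster = 0), ">= 1")
  # whole-cluster request returns the cluster in distance order
  reps3 <- select_representatives(km2, d2, m_per_cluster = 2)
  sizes <- vapply(reps3$per_cluster, nrow, integer(1))
  expect_equal(sort(sizes), c(1, 2))
})
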