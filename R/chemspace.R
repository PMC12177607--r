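# Descriptor-matrix processing, PCA, K-means clustering with
# information-criterion / quality-index cluster-number selection, and
# centroid-proximity representative selection.

#' Construct a descriptor matrix
#'
#' @param values n x d numeric matrix of descriptor values.
#' @param ids Molecule identifiers (names and/or SMILES), length n.
#' @param smiles Optional SMILES strings, length n.
#' @param provenance Free-text provenance note.
#' @return A `descriptor_matrix`.
#' @export
descriptor_matrix <- function(values, ids = NULL, smiles = NULL,
                              provenance = "") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("D", seq_len(ncol(values)))
  }
  if (anyDuplicated(colnames(values))) stop("descriptor names must be unique")
  if (is.null(ids)) ids <- paste0("mol", seq_len(nrow(values)))
  stopifnot(length(ids) == nrow(values))
  structure(list(ids = as.character(ids), smiles = smiles,
                 values = values, provenance = provenance),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("descriptor_matrix: %d molecules x %d descriptors\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a descriptor CSV
#'
#' Expected layout: first column molecule id, optional second column
#' `smiles`, remaining columns numeric descriptors.
#'
#' @param path CSV path.
#' @return A `descriptor_matrix`.
#' @export
read_descriptors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("descriptor CSV needs an id column plus descriptors")
  ids <- as.character(df[[1]])
  smiles <- NULL
  start <- 2
  if (tolower(names(df)[2]) == "smiles") { smiles <- df[[2]]; start <- 3 }
  vals <- as.matrix(df[, start:ncol(df), drop = FALSE])
  storage.mode(vals) <- "double"
  descriptor_matrix(vals, ids = ids, smiles = smiles, provenance = path)
}

#' Drop non-finite and constant descriptor columns
#'
#' @param dm A `descriptor_matrix`.
#' @return A cleaned `descriptor_matrix`; dropped columns are reported via
#'   message. All columns dropped is an error.
#' @export
clean_descriptors <- function(dm) {
  v <- dm$values
  bad <- vapply(seq_len(ncol(v)), function(j) {
    any(!is.finite(v[, j])) || stats::sd(v[, j]) == 0
  }, logical(1))
  if (all(bad)) stop("all descriptor columns dropped during cleaning")
  if (any(bad)) {
    message("dropped ", sum(bad), " non-finite/constant descriptor(s): ",
            paste(colnames(v)[bad], collapse = ", "))
  }
  dm$values <- v[, !bad, drop = FALSE]
  dm
}

#' Filter collinear descriptors by Pearson correlation
#'
#' Scans columns in order and drops any column whose absolute Pearson
#' correlation with an already-kept column exceeds the threshold
#' (deterministic keep-first policy), reducing redundancy before PCA.
#'
#' @param dm A cleaned `descriptor_matrix`.
#' @param threshold Absolute correlation threshold (default 0.95).
#' @return List with `dm` (filtered matrix) and `dropped` (column names).
#' @export
correlation_filter <- function(dm, threshold = 0.95) {
  v <- dm$values
  kept <- integer(0)
  dropped <- character(0)
  for (j in seq_len(ncol(v))) {
    collinear <- FALSE
    for (k in kept) {
      if (abs(stats::cor(v[, j], v[, k])) > threshold) { collinear <- TRUE; break }
    }
    if (collinear) dropped <- c(dropped, colnames(v)[j]) else kept <- c(kept, j)
  }
  dm$values <- v[, kept, drop = FALSE]
  list(dm = dm, dropped = dropped)
}

#' Principal component analysis of a descriptor matrix
#'
#' Columns are standardised (z-score) before the decomposition; components
#' are ordered by decreasing variance with the sign convention that each
#' component's largest-magnitude loading is positive.
#'
#' @param dm A `descriptor_matrix` (cleaned).
#' @param m Number of components to retain, or a fraction in (0, 1)
#'   interpreted as a cumulative explained-variance target. Default 2.
#' @return A `pca_result`: `loadings` (d x m), `explained` (variance ratios
#'   of the retained components), `scores` (n x m), `m`, `center`, `scale`.
#' @export
pca_descriptors <- function(dm, m = 2) {
  v <- dm$values
  pr <- stats::prcomp(v, center = TRUE, scale. = TRUE)
  ratios <- pr$sdev^2 / sum(pr$sdev^2)
  rank <- sum(pr$sdev > 1e-10)
  if (m > 0 && m < 1) {
    m_use <- which(cumsum(ratios) >= m)[1]
  } else {
    m_use <- as.integer(m)
    if (m_use > rank) stop("m exceeds the rank of the descriptor matrix")
  }
  keep <- seq_len(m_use)
  load <- pr$rotation[, keep, drop = FALSE]
  scores <- pr$x[, keep, drop = FALSE]
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(loadings = load, explained = ratios[keep], scores = scores,
                 m = m_use, center = pr$center, scale = pr$scale,
                 all_ratios = ratios, ids = dm$ids),
            class = "pca_result")
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  chosen <- logical(n)
  i <- sample.int(n, 1)
  chosen[i] <- TRUE
  centers[1, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    if (sum(d2) == 0) {
      # all remaining mass on already-chosen points (duplicates or k = n):
      # fall back to an unchosen point so centers stay distinct
      pool <- which(!chosen)
      i <- if (length(pool) == 1) pool else sample(pool, 1)
    } else {
      i <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    chosen[i] <- TRUE
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

lloyd <- function(X, centers, max_iter = 200, tol = 1e-8) {
  k <- nrow(centers)
  n <- nrow(X)
  labels <- integer(n)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    D <- vapply(seq_len(k), function(j)
      rowSums(sweep(X, 2, centers[j, ])^2), numeric(n))
    labels <- apply(D, 1, which.min)  # exact nearest centre, no tie fuzz
    new_centers <- centers
    for (j in seq_len(k)) {
      mem <- labels == j
      if (!any(mem)) {
        # empty-cluster repair: reseed at the point farthest from its centroid
        far <- which.max(D[cbind(seq_len(n), labels)])
        new_centers[j, ] <- X[far, ]
        labels[far] <- j
      } else {
        new_centers[j, ] <- colMeans(X[mem, , drop = FALSE])
      }
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) { converged <- TRUE; break }
  }
  D <- vapply(seq_len(k), function(j)
    rowSums(sweep(X, 2, centers[j, ])^2), numeric(n))
  labels <- apply(D, 1, which.min)
  for (j in seq_len(k)) {
    mem <- labels == j
    if (any(mem)) centers[j, ] <- colMeans(X[mem, , drop = FALSE])
  }
  wcss <- sum(rowSums((X - centers[labels, , drop = FALSE])^2))
  list(labels = labels, centers = centers, wcss = wcss, converged = converged)
}

#' K-means clustering (k-means++ / Lloyd, multiple restarts)
#'
#' Minimises the within-cluster sum of squares
#' WCSS = sum_j sum_{i in j} ||x_i - c_j||^2 by Lloyd iterations from
#' k-means++ seeding, keeping the best of `n_init` restarts. Empty clusters
#' are repaired by reseeding at the point farthest from its centroid.
#'
#' @param X n x m numeric matrix (typically PCA scores).
#' @param k Number of clusters, 1 <= k <= n.
#' @param seed RNG seed (restarts are drawn inside one seeded stream).
#' @param n_init Number of restarts (default 10).
#' @return A `kmeans_result`: `k`, `labels` (1..k), `centroids` (k x m),
#'   `wcss`, `seed`, `n_init`, `converged`.
#' @export
kmeans_cluster <- function(X, k, seed = 1, n_init = 10) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k must not exceed the number of points")
  best <- NULL
  with_local_seed(seed, {
    for (i in seq_len(n_init)) {
      fit <- lloyd(X, kmeanspp_init(X, k))
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
  })
  structure(list(k = k, labels = best$labels, centroids = best$centers,
                 wcss = best$wcss, seed = seed, n_init = n_init,
                 converged = best$converged),
            class = "kmeans_result")
}

#' Within-cluster sum of squares of a clustering
#'
#' Evaluates the K-means objective for given points, labels and centroids;
#' identical to the WCSS stored in a [kmeans_cluster()] result.
#'
#' @param X n x m matrix.
#' @param labels Cluster assignments (1..k).
#' @param centroids k x m centroid matrix.
#' @return Scalar WCSS.
#' @export
wcss_objective <- function(X, labels, centroids) {
  sum(rowSums((as.matrix(X) - centroids[labels, , drop = FALSE])^2))
}

#' Cluster quality indices for a K-means solution
#'
#' Computes the Gaussian-likelihood information criteria and the internal
#' quality indices used for cluster-number selection:
#' ln L = -(n m / 2) (ln(2 pi sigma2) + 1) with sigma2 = WCSS / (n m)
#' (isotropic maximum-likelihood policy), parameter count p = k m + 1
#' (centroids plus a shared variance), AIC = 2 p - 2 ln L,
#' BIC = p ln n - 2 ln L; mean silhouette (singleton points scored 0 and
#' flagged); Davies-Bouldin with sigma_i the mean member-centroid distance;
#' Calinski-Harabasz from the between/within dispersion traces.
#'
#' @param X n x m matrix the clustering was fitted on.
#' @param km A `kmeans_result`.
#' @return A `cluster_quality` list: `k`, `wcss`, `sigma2`, `logL`, `p`,
#'   `aic`, `bic`, `silhouette` (mean), `sil_points` (per-point s(i)),
#'   `davies_bouldin`, `calinski_harabasz`, `has_singleton`. For k = 1 the
#'   three indices are NA.
#' @export
cluster_quality <- function(X, km) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X); k <- km$k
  wcss <- km$wcss
  sigma2 <- wcss / (n * m)
  logL <- if (sigma2 > 0) -(n * m / 2) * (log(2 * pi * sigma2) + 1) else Inf
  p <- k * m + 1
  aic <- 2 * p - 2 * logL
  bic <- p * log(n) - 2 * logL
  sil <- rep(NA_real_, n); db <- NA_real_; ch <- NA_real_
  has_singleton <- FALSE
  if (k >= 2) {
    Dmat <- as.matrix(stats::dist(X))
    sizes <- tabulate(km$labels, k)
    has_singleton <- any(sizes == 1)
    for (i in seq_len(n)) {
      own <- km$labels[i]
      if (sizes[own] == 1) { sil[i] <- 0; next }
      a_i <- sum(Dmat[i, km$labels == own]) / (sizes[own] - 1)
      b_i <- min(vapply(setdiff(seq_len(k), own), function(j)
        mean(Dmat[i, km$labels == j]), numeric(1)))
      sil[i] <- (b_i - a_i) / max(a_i, b_i)
    }
    cd <- vapply(seq_len(k), function(j)
      mean(sqrt(rowSums(sweep(X[km$labels == j, , drop = FALSE], 2,
                              km$centroids[j, ])^2))), numeric(1))
    cc <- as.matrix(stats::dist(km$centroids))
    db <- mean(vapply(seq_len(k), function(i)
      max(vapply(setdiff(seq_len(k), i), function(j)
        (cd[i] + cd[j]) / cc[i, j], numeric(1))), numeric(1)))
    grand <- colMeans(X)
    trB <- sum(sizes * rowSums(sweep(km$centroids, 2, grand)^2))
    trW <- wcss
    ch <- (trB / trW) * ((n - k) / (k - 1))
  }
  structure(list(k = k, wcss = wcss, sigma2 = sigma2, logL = logL, p = p,
                 aic = aic, bic = bic,
                 silhouette = mean(sil), sil_points = sil,
                 davies_bouldin = db, calinski_harabasz = ch,
                 has_singleton = has_singleton),
            class = "cluster_quality")
}

#' Select the number of clusters by consensus of five criteria
#'
#' Runs [kmeans_cluster()] and [cluster_quality()] for each k in `k_range`
#' and picks the consensus k as the mode of {argmin AIC, argmin BIC,
#' argmin Davies-Bouldin, argmax silhouette, argmax Calinski-Harabasz};
#' ties are broken in favour of the BIC winner. The full per-k table is
#' returned for elbow (WCSS) inspection, with a `weak_structure` diagnostic
#' flag raised when the best silhouette over the range stays below 0.3.
#'
#' @param X n x m matrix.
#' @param k_range Integer vector of candidate k (default 2:10).
#' @param seed RNG seed.
#' @param n_init Restarts per k.
#' @return List with `k` (chosen), `table` (per-k data frame of wcss, aic,
#'   bic, silhouette, davies_bouldin, calinski_harabasz), `votes`,
#'   `weak_structure`, and `fits` (the per-k `kmeans_result`s).
#' @export
select_k <- function(X, k_range = 2:10, seed = 1, n_init = 10) {
  X <- as.matrix(X)
  if (length(k_range) == 0) stop("empty k_range")
  if (any(k_range < 2) || any(k_range > nrow(X) - 1)) {
    stop("k_range must lie within [2, n-1]")
  }
  fits <- list(); quals <- list()
  for (i in seq_along(k_range)) {
    fits[[i]] <- kmeans_cluster(X, k_range[i], seed = seed + k_range[i],
                                n_init = n_init)
    quals[[i]] <- cluster_quality(X, fits[[i]])
  }
  tab <- data.frame(
    k = k_range,
    wcss = vapply(quals, `[[`, numeric(1), "wcss"),
    aic = vapply(quals, `[[`, numeric(1), "aic"),
    bic = vapply(quals, `[[`, numeric(1), "bic"),
    silhouette = vapply(quals, `[[`, numeric(1), "silhouette"),
    davies_bouldin = vapply(quals, `[[`, numeric(1), "davies_bouldin"),
    calinski_harabasz = vapply(quals, `[[`, numeric(1), "calinski_harabasz")
  )
  votes <- c(
    aic = tab$k[which.min(tab$aic)],
    bic = tab$k[which.min(tab$bic)],
    davies_bouldin = tab$k[which.min(tab$davies_bouldin)],
    silhouette = tab$k[which.max(tab$silhouette)],
    calinski_harabasz = tab$k[which.max(tab$calinski_harabasz)]
  )
  counts <- table(votes)
  winners <- as.integer(names(counts)[counts == max(counts)])
  chosen <- if (length(winners) == 1) winners
    else if (votes[["bic"]] %in% winners) votes[["bic"]]  # BIC breaks ties
    else winners[which.min(tab$bic[match(winners, tab$k)])]
  # Kaufman-Rousseeuw reading of the silhouette: <= 0.50 means weak or
  # artificial structure, so a range whose best silhouette stays below 0.5
  # is flagged as having no convincing cluster structure
  list(k = chosen, table = tab, votes = votes,
       weak_structure = max(tab$silhouette, na.rm = TRUE) < 0.5,
       fits = stats::setNames(fits, paste0("k", k_range)))
}

#' Distance of each point to its own cluster centroid
#'
#' d_i = sqrt(sum_j (x_ij - c_j)^2) in the (PCA-reduced) clustering space.
#'
#' @param scores n x m matrix of coordinates.
#' @param km A `kmeans_result`.
#' @return Numeric vector of length n.
#' @export
centroid_distances <- function(scores, km) {
  X <- as.matrix(scores)
  sqrt(rowSums((X - km$centroids[km$labels, , drop = FALSE])^2))
}

#' Select representative molecules nearest each cluster centroid
#'
#' Per cluster, the `m_per_cluster` molecules with the smallest centroid
#' distance are returned in increasing-distance order (ties by input
#' order). Clusters smaller than `m_per_cluster` return all their members
#' and are flagged as truncated.
#'
#' @param km A `kmeans_result`.
#' @param distances From [centroid_distances()].
#' @param m_per_cluster Molecules per cluster (default 4, >= 1).
#' @param ids Optional molecule ids (default row indices as strings).
#' @return A `representative_set`: list with `per_cluster` (data frames of
#'   id, index, distance), `m_per_cluster`, `total`, `truncated` (cluster
#'   ids smaller than requested).
#' @export
select_representatives <- function(km, distances, m_per_cluster = 4,
                                   ids = NULL) {
  if (m_per_cluster < 1) stop("m_per_cluster must be >= 1")
  n <- length(distances)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  per <- list(); truncated <- integer(0)
  for (j in seq_len(km$k)) {
    idx <- which(km$labels == j)
    ord <- idx[order(distances[idx], idx)]
    take <- utils::head(ord, m_per_cluster)
    if (length(idx) < m_per_cluster) truncated <- c(truncated, j)
    per[[j]] <- data.frame(cluster = j, id = ids[take], index = take,
                           distance = distances[take],
                           stringsAsFactors = FALSE)
  }
  structure(list(per_cluster = per, m_per_cluster = m_per_cluster,
                 total = sum(vapply(per, nrow, integer(1))),
                 truncated = truncated),
            class = "representative_set")
}

#' @export
print.representative_set <- function(x, ...) {
  cat(sprintf("representative_set: %d molecules (%d per cluster requested)\n",
              x$total, x$m_per_cluster))
  invisible(x)
}

#' @export
as.data.frame.representative_set <- function(x, ...) {
  do.call(rbind, x$per_cluster)
}
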