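# Clustering of embedded events and internal validity indices.
#
# Three algorithms (k-means with k-means++ seeding, Ward agglomerative,
# spectral) and three indices (silhouette, Calinski-Harabasz,
# Davies-Bouldin) computed in the embedding space. The indices are
# implemented directly from their defining formulas; tests cross-check them
# against brute-force and third-party implementations.

# --- label canonicalization -------------------------------------------------

# Centroid matrix (one row per id), robust to 1-D inputs.
centroid_matrix <- function(x, labels, ids) {
  out <- matrix(0, length(ids), ncol(x))
  for (j in seq_along(ids))
    out[j, ] <- colMeans(x[labels == ids[j], , drop = FALSE])
  out
}

# Relabel clusters 0..k-1 by descending size; ties broken by lexicographic
# order of cluster centroids. Makes labels deterministic given a partition.
canonicalize_labels <- function(labels, points) {
  points <- as.matrix(points)
  ids <- sort(unique(labels))
  sizes <- vapply(ids, function(i) sum(labels == i), numeric(1))
  cent <- centroid_matrix(points, labels, ids)
  ord <- do.call(order, c(list(-sizes), as.data.frame(cent)))
  new_of_old <- integer(length(ids))
  new_of_old[ord] <- seq_along(ids) - 1L
  new_of_old[match(labels, ids)]
}

# --- k-means ----------------------------------------------------------------

# k-means++ seeding (Arthur & Vassilvitskii) drawing from the current RNG.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- x[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
  }
  centers
}

#' K-means clustering with k-means++ seeding and multiple restarts
#'
#' Runs `n_init` seeded k-means++ initializations followed by Lloyd
#' iterations (via [stats::kmeans()]), keeps the lowest-inertia solution and
#' canonicalizes labels (descending cluster size, centroid order on ties) so
#' the result is deterministic given `(input, seed)`.
#'
#' @param coords Numeric matrix (events x dims), typically the UMAP
#'   embedding.
#' @param k Number of clusters (default 5).
#' @param n_init Number of restarts (default 20).
#' @param seed Integer seed.
#' @param compute_metrics Attach silhouette/CH/DB metrics (default TRUE).
#' @return A list of class `"peg_clustering"`: `algorithm`, `k`, `labels`
#'   (integers `0..k-1`), `centers`, `inertia`, `metrics`, `seed`.
#' @export
kmeans_cluster <- function(coords, k = 5, n_init = 20, seed = 0,
                           compute_metrics = TRUE) {
  x <- as.matrix(coords)
  if (nrow(x) <= k) stop("need more points than clusters")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      ctrs <- kmeanspp_centers(x, k)
      fit <- suppressWarnings(
        stats::kmeans(x, centers = ctrs, iter.max = 100, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  labels <- canonicalize_labels(best$cluster - 1L, x)
  finish_clustering("kmeans", x, labels, k, seed, best$tot.withinss,
                    compute_metrics)
}

# shared tail: recompute centers from canonical labels, attach metrics
finish_clustering <- function(algorithm, x, labels, k, seed, inertia,
                              compute_metrics) {
  centers <- centroid_matrix(x, labels, 0:(k - 1))
  metrics <- if (compute_metrics) {
    list(silhouette = silhouette_score(x, labels),
         calinski_harabasz = calinski_harabasz(x, labels),
         davies_bouldin = davies_bouldin(x, labels))
  } else NULL
  structure(list(algorithm = algorithm, k = k, labels = labels,
                 centers = centers, inertia = inertia, metrics = metrics,
                 seed = seed),
            class = "peg_clustering")
}

#' @export
print.peg_clustering <- function(x, ...) {
  cat(sprintf("<peg_clustering> %s, k = %d, n = %d\n", x$algorithm, x$k,
              length(x$labels)))
  if (!is.null(x$metrics))
    cat(sprintf("  S = %.3f | CH = %.1f | DB = %.3f\n",
                x$metrics$silhouette, x$metrics$calinski_harabasz,
                x$metrics$davies_bouldin))
  invisible(x)
}

#' Agglomerative clustering with Ward's linkage
#'
#' Bottom-up Ward merges on Euclidean distances ([stats::hclust()] method
#' `"ward.D2"`), cut at `k` clusters. Deterministic.
#'
#' @inheritParams kmeans_cluster
#' @export
agglomerative_cluster <- function(coords, k = 5, compute_metrics = TRUE) {
  x <- as.matrix(coords)
  if (nrow(x) < k) stop("need at least k points")
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  labels <- canonicalize_labels(stats::cutree(hc, k = k) - 1L, x)
  finish_clustering("agglomerative", x, labels, k, seed = NA_integer_,
                    inertia = NA_real_, compute_metrics)
}

#' Spectral clustering via the symmetric-normalized graph Laplacian
#'
#' Builds a symmetric k-nearest-neighbor similarity graph with self-tuning
#' Gaussian weights (`w_ij = exp(-d_ij^2 / (sigma_i sigma_j))`, where
#' `sigma_i` is the distance to the `n_neighbors`-th neighbor), takes the
#' bottom `k` eigenvectors of `L_sym = I - D^{-1/2} A D^{-1/2}`,
#' row-normalizes them and applies [kmeans_cluster()]. Errors if the
#' neighbor graph is disconnected (raise `n_neighbors`).
#'
#' @inheritParams kmeans_cluster
#' @param n_neighbors Neighborhood size of the graph (default 10).
#' @param n_init k-means restarts on the spectral coordinates.
#' @export
spectral_cluster <- function(coords, k = 5, n_neighbors = 10, n_init = 20,
                             seed = 0, compute_metrics = TRUE) {
  x <- as.matrix(coords)
  n <- nrow(x)
  if (n <= k) stop("need more points than clusters")
  if (n_neighbors >= n) stop("n_neighbors must be < number of points")
  knn <- FNN::get.knn(x, k = n_neighbors)
  sigma <- pmax(knn$nn.dist[, n_neighbors], 1e-12)  # local scale per point
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- knn$nn.index[i, ]
    A[i, j] <- exp(-knn$nn.dist[i, ]^2 / (sigma[i] * sigma[j]))
  }
  A <- pmax(A, t(A))  # symmetric (union) kNN graph
  # connectivity check by BFS
  seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(A[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen))
    stop("kNN graph is disconnected; raise n_neighbors")
  d <- rowSums(A)
  Dhalf <- 1 / sqrt(d)
  Lsym <- diag(n) - (Dhalf * A) * rep(Dhalf, each = n)  # D^-1/2 A D^-1/2
  eig <- eigen(Lsym, symmetric = TRUE)
  U <- eig$vectors[, n:(n - k + 1), drop = FALSE]  # bottom-k eigenvectors
  norms <- sqrt(rowSums(U^2))
  norms[norms == 0] <- 1
  U <- U / norms
  fit <- kmeans_cluster(U, k = k, n_init = n_init, seed = seed,
                        compute_metrics = FALSE)
  labels <- canonicalize_labels(fit$labels, x)
  finish_clustering("spectral", x, labels, k, seed, NA_real_, compute_metrics)
}

# --- validity indices -------------------------------------------------------

as_dist_matrix <- function(points_or_dist) {
  if (inherits(points_or_dist, "dist")) return(as.matrix(points_or_dist))
  if (is.matrix(points_or_dist) && isSymmetric(unname(points_or_dist)) &&
      all(diag(points_or_dist) == 0) && ncol(points_or_dist) == nrow(points_or_dist) &&
      !is.null(attr(points_or_dist, "is_dist")))
    return(points_or_dist)
  as.matrix(stats::dist(as.matrix(points_or_dist)))
}

#' Silhouette score
#'
#' Per sample, `s_i = (b_i - a_i) / max(a_i, b_i)` where `a_i` is the mean
#' distance to other members of its own cluster and `b_i` the smallest mean
#' distance to another cluster. Samples in singleton clusters score 0. The
#' score is the mean over samples. Euclidean distances by default; pass a
#' `dist` object to use any precomputed metric.
#'
#' @param points Numeric matrix, or a [stats::dist()] object.
#' @param labels Integer label vector.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(points, labels) {
  ids <- sort(unique(labels))
  if (length(ids) < 2) stop("need at least 2 clusters")
  D <- as_dist_matrix(points)
  n <- length(labels)
  member <- outer(labels, ids, "==")          # n x k indicator
  sizes <- colSums(member)
  sums <- D %*% member                        # n x k: sum of distances to each cluster
  own <- match(labels, ids)
  a_den <- sizes[own] - 1
  a <- ifelse(a_den > 0, sums[cbind(seq_len(n), own)] / a_den, NA_real_)
  meand <- sweep(sums, 2, sizes, "/")
  meand[cbind(seq_len(n), own)] <- Inf
  b <- apply(meand, 1, min)
  s <- ifelse(sizes[own] == 1, 0, (b - a) / pmax(a, b))
  s[is.nan(s)] <- 0                           # a = b = 0 (coincident clusters)
  mean(s)
}

#' Calinski-Harabasz index
#'
#' `CH = (tr(B) / tr(W)) * ((N - k) / (k - 1))` with between/within
#' dispersion traces about the global/cluster centroids. Zero within-cluster
#' dispersion yields `Inf` with attribute `degenerate = TRUE`.
#'
#' @param points Numeric matrix (events x dims).
#' @param labels Integer label vector.
#' @return CH index (>= 0, possibly `Inf`).
#' @export
calinski_harabasz <- function(points, labels) {
  x <- as.matrix(points)
  ids <- sort(unique(labels))
  k <- length(ids)
  if (k < 2) stop("need at least 2 clusters")
  n <- nrow(x)
  global <- colMeans(x)
  tr_w <- 0; tr_b <- 0
  for (i in ids) {
    xi <- x[labels == i, , drop = FALSE]
    ci <- colMeans(xi)
    tr_w <- tr_w + sum(sweep(xi, 2, ci)^2)
    tr_b <- tr_b + nrow(xi) * sum((ci - global)^2)
  }
  if (tr_w == 0) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (tr_b / tr_w) * ((n - k) / (k - 1))
}

#' Davies-Bouldin index
#'
#' `DB = (1/k) sum_i max_{j != i} (s_i + s_j) / d(c_i, c_j)` where `s_i` is
#' the mean distance of cluster members to their centroid. Coincident
#' centroids yield `Inf` with attribute `degenerate = TRUE`.
#'
#' @inheritParams calinski_harabasz
#' @return DB index (>= 0, lower is better).
#' @export
davies_bouldin <- function(points, labels) {
  x <- as.matrix(points)
  ids <- sort(unique(labels))
  k <- length(ids)
  if (k < 2) stop("need at least 2 clusters")
  cents <- centroid_matrix(x, labels, ids)
  scatter <- vapply(seq_along(ids), function(j) {
    xi <- x[labels == ids[j], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cents[j, ])^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(cents))
  if (any(cd[upper.tri(cd)] == 0)) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  R <- outer(scatter, scatter, "+") / cd
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}
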