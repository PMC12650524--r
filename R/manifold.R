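# Dimensionality reduction: PCA to 30 components, then a 10-dimensional
# UMAP embedding (cosine metric, 35 neighbors, min_dist 0.01), plus the
# hyperparameter sensitivity grid used to check that cluster assignments do
# not depend delicately on the embedding parameters.

#' PCA reduction of a standardized feature matrix
#'
#' Centered (not re-scaled) PCA retaining exactly `n_components` components.
#' Component signs follow a deterministic convention: the largest-magnitude
#' loading of each component is positive. A warning is issued when the
#' retained components explain less than `variance_target` of the total
#' variance.
#'
#' @param fm Standardized feature matrix (events x features).
#' @param n_components Number of components to retain (default 30).
#' @param variance_target Cumulative explained-variance check level
#'   (default 0.95).
#' @return A list of class `"peg_pca"`: `scores` (events x n_components),
#'   `explained_variance_ratio` (length `n_components`),
#'   `cumulative_variance`, `rotation`, `center`.
#' @export
pca_reduce <- function(fm, n_components = 30, variance_target = 0.95) {
  x <- unclass(fm)
  if (nrow(x) < n_components)
    stop("need at least ", n_components, " rows for ", n_components, " components")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (sum(pc$sdev^2) < 1e-300)
    stop("feature matrix has zero variance; nothing to reduce")
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  flip <- vapply(seq_len(k), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, "*")
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  evr_k <- evr[seq_len(k)]
  if (k < n_components) {
    evr_k <- c(evr_k, rep(0, n_components - k))
    scores <- cbind(scores, matrix(0, nrow(scores), n_components - k))
  }
  cum <- sum(evr_k)
  if (cum < variance_target)
    warning(sprintf("retained %d components explain %.1f%% < %.0f%% of variance",
                    n_components, 100 * cum, 100 * variance_target))
  colnames(scores) <- sprintf("PC%d", seq_len(ncol(scores)))
  structure(list(scores = scores, explained_variance_ratio = evr_k,
                 cumulative_variance = cum, rotation = rot, center = pc$center),
            class = "peg_pca")
}

#' UMAP embedding of PCA scores
#'
#' Thin, seeded wrapper around [uwot::umap()] run single-threaded so that a
#' fixed seed reproduces coordinates exactly run-to-run on one platform.
#'
#' @param scores Numeric matrix (events x dims), typically PCA scores.
#' @param n_neighbors Neighborhood size (default 35).
#' @param min_dist Minimum embedding distance (default 0.01).
#' @param metric Distance metric (default `"cosine"`).
#' @param n_components Embedding dimension (default 10).
#' @param seed Integer seed (default 0).
#' @return Numeric matrix (events x `n_components`).
#' @export
umap_embed <- function(scores, n_neighbors = 35, min_dist = 0.01,
                       metric = "cosine", n_components = 10, seed = 0) {
  scores <- as.matrix(scores)
  if (nrow(scores) < n_neighbors + 1)
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1, " rows")
  coords <- uwot::umap(scores, n_neighbors = n_neighbors, min_dist = min_dist,
                       metric = metric, n_components = n_components,
                       seed = seed, n_threads = 1, n_sgd_threads = 0)
  colnames(coords) <- sprintf("UMAP%d", seq_len(ncol(coords)))
  coords
}

#' Adjusted Rand Index between two partitions
#'
#' Implemented from the contingency-table formula:
#' `ARI = (sum_ij C(n_ij,2) - E) / (max - E)` with
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)`. Label symbols are
#' irrelevant; identical partitions give 1, independent ones about 0.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  n <- length(a)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' UMAP hyperparameter sensitivity grid
#'
#' Re-embeds `scores` at each (n_neighbors, min_dist) grid point, clusters
#' the embedding with k-means and reports the silhouette of that clustering
#' together with the ARI of its labels against the baseline configuration's
#' labels.
#'
#' @param scores PCA scores (events x dims).
#' @param neighbors_grid Integer vector of `n_neighbors` values.
#' @param min_dist_grid Numeric vector of `min_dist` values.
#' @param baseline List with `n_neighbors` and `min_dist` of the reference
#'   configuration (default 35 / 0.01).
#' @param k Number of clusters (default 5).
#' @param n_init k-means restarts (default 20).
#' @param metric UMAP metric (default `"cosine"`).
#' @param n_components Embedding dimension (default 10).
#' @param seed Integer seed used for every embedding and clustering.
#' @return A `data.frame` with columns `n_neighbors`, `min_dist`,
#'   `silhouette`, `ari_vs_baseline`, including the baseline row (ARI 1 by
#'   construction).
#' @export
sensitivity_grid <- function(scores, neighbors_grid = c(15, 25, 35, 50),
                             min_dist_grid = c(0.001, 0.01, 0.1),
                             baseline = list(n_neighbors = 35, min_dist = 0.01),
                             k = 5, n_init = 20, metric = "cosine",
                             n_components = 10, seed = 0) {
  embed_cluster <- function(nn, md) {
    coords <- umap_embed(scores, n_neighbors = nn, min_dist = md,
                         metric = metric, n_components = n_components,
                         seed = seed)
    fit <- kmeans_cluster(coords, k = k, n_init = n_init, seed = seed,
                          compute_metrics = FALSE)
    list(coords = coords, labels = fit$labels)
  }
  base_fit <- embed_cluster(baseline$n_neighbors, baseline$min_dist)
  grid <- expand.grid(n_neighbors = neighbors_grid, min_dist = min_dist_grid,
                      KEEP.OUT.ATTRS = FALSE)
  is_base <- grid$n_neighbors == baseline$n_neighbors &
    grid$min_dist == baseline$min_dist
  if (!any(is_base)) {
    grid <- rbind(grid, data.frame(n_neighbors = baseline$n_neighbors,
                                   min_dist = baseline$min_dist))
    is_base <- c(is_base, TRUE)
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    fit <- if (is_base[i]) base_fit else
      embed_cluster(grid$n_neighbors[i], grid$min_dist[i])
    data.frame(
      n_neighbors = grid$n_neighbors[i],
      min_dist = grid$min_dist[i],
      silhouette = silhouette_score(fit$coords, fit$labels),
      ari_vs_baseline = adjusted_rand_index(fit$labels, base_fit$labels)
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
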