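# Robustness battery for the clustering solution: permutation test of the
# silhouette, bootstrap model selection over k, leave-one-subject-out
# stability, and seed-repeat membership variability.

#' Permutation test of the observed silhouette
#'
#' Permutes labels `n` times (preserving cluster sizes), recomputes the
#' silhouette for each permutation, and reports the one-sided p-value
#' `p = (1 + #\{null >= observed\}) / (1 + n)`, whose smallest attainable
#' value is `1 / (n + 1)`.
#'
#' @param points Numeric matrix (events x dims) or a [stats::dist()] object.
#' @param labels Integer label vector.
#' @param n Number of permutations (default 300).
#' @param seed Integer seed.
#' @return A list of class `"peg_permutation"`: `observed`, `null` (length
#'   `n`), `p_value`, `n`.
#' @export
permutation_test <- function(points, labels, n = 300, seed = 0) {
  D <- stats::as.dist(as_dist_matrix(points))
  observed <- silhouette_score(D, labels)
  null <- with_seed(seed, vapply(seq_len(n), function(i)
    silhouette_score(D, sample(labels)), numeric(1)))
  p <- (1 + sum(null >= observed)) / (1 + n)
  structure(list(observed = observed, null = null, p_value = p, n = n),
            class = "peg_permutation")
}

#' Bootstrap selection of the number of clusters
#'
#' Draws `n` bootstrap resamples (with replacement); for each resample and
#' each `k` in `k_range` fits k-means and records silhouette, CH and DB.
#' Returns mean and SD of each metric per k, plus the k with the best mean
#' silhouette.
#'
#' @param points Numeric matrix (events x dims).
#' @param k_range Candidate cluster counts (default `3:7`).
#' @param n Number of bootstrap resamples (default 200).
#' @param n_init k-means restarts per fit (default 20).
#' @param seed Integer seed.
#' @return A list of class `"peg_bootstrap"`: `summary` (data.frame with
#'   mean/sd of S, CH, DB per k), `best_k` (argmax of mean silhouette),
#'   `n`, `k_range`.
#' @export
bootstrap_k_selection <- function(points, k_range = 3:7, n = 200, n_init = 20,
                                  seed = 0) {
  x <- as.matrix(points)
  N <- nrow(x)
  stopifnot(N > max(k_range))
  S <- CH <- DB <- matrix(NA_real_, n, length(k_range),
                          dimnames = list(NULL, paste0("k", k_range)))
  for (b in seq_len(n)) {
    idx <- with_seed(child_seed(seed, b), sample.int(N, N, replace = TRUE))
    xb <- x[idx, , drop = FALSE]
    Db <- stats::as.dist(as_dist_matrix(xb))
    for (j in seq_along(k_range)) {
      fit <- kmeans_cluster(xb, k = k_range[j], n_init = n_init,
                            seed = child_seed(seed, b * 1000 + j),
                            compute_metrics = FALSE)
      S[b, j] <- silhouette_score(Db, fit$labels)
      CH[b, j] <- calinski_harabasz(xb, fit$labels)
      DB[b, j] <- davies_bouldin(xb, fit$labels)
    }
  }
  summ <- data.frame(
    k = k_range,
    silhouette_mean = colMeans(S), silhouette_sd = apply(S, 2, stats::sd),
    ch_mean = colMeans(CH), ch_sd = apply(CH, 2, stats::sd),
    db_mean = colMeans(DB), db_sd = apply(DB, 2, stats::sd)
  )
  rownames(summ) <- NULL
  structure(list(summary = summ,
                 best_k = k_range[which.max(summ$silhouette_mean)],
                 n = n, k_range = k_range),
            class = "peg_bootstrap")
}

#' Leave-one-subject-out clustering stability
#'
#' For each subject, events of that subject are held out, the remaining
#' events are reclustered with k-means in the same embedding space, and the
#' new labels of the retained events are compared to the full-data labels
#' via ARI.
#'
#' @param points Numeric matrix (events x dims).
#' @param labels Full-data cluster labels.
#' @param subject_ids Per-event subject identifiers.
#' @param k Number of clusters (default: number of distinct labels).
#' @param n_init k-means restarts (default 20).
#' @param seed Integer seed.
#' @return A `data.frame` with columns `subject` and `ari`.
#' @export
loso_stability <- function(points, labels, subject_ids,
                           k = length(unique(labels)), n_init = 20, seed = 0) {
  x <- as.matrix(points)
  subjects <- unique(subject_ids)
  if (length(subjects) < 2) stop("need at least 2 subjects")
  res <- lapply(seq_along(subjects), function(i) {
    keep <- subject_ids != subjects[i]
    if (!any(keep)) stop("subject ", subjects[i], " owns all events")
    fit <- kmeans_cluster(x[keep, , drop = FALSE], k = k, n_init = n_init,
                          seed = child_seed(seed, i), compute_metrics = FALSE)
    data.frame(subject = as.character(subjects[i]),
               ari = adjusted_rand_index(fit$labels, labels[keep]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Seed-repeat membership variability
#'
#' Repeats the embedding + k-means pipeline under different seeds and
#' reports the proportion of events whose cluster membership changes
#' relative to the first repeat, after optimally matching cluster labels
#' (exhaustive permutation matching, valid for small k).
#'
#' @param scores PCA scores (events x dims).
#' @param k Number of clusters (default 5).
#' @param seeds Integer vector of seeds (default `0:4`).
#' @param n_neighbors,min_dist,metric,n_components UMAP parameters.
#' @param n_init k-means restarts.
#' @return A list: `disagreement` (per non-reference seed), `max`, `mean`.
#' @export
seed_repeat_variability <- function(scores, k = 5, seeds = 0:4,
                                    n_neighbors = 35, min_dist = 0.01,
                                    metric = "cosine", n_components = 10,
                                    n_init = 20) {
  stopifnot(length(seeds) >= 2)
  run <- function(s) {
    coords <- umap_embed(scores, n_neighbors, min_dist, metric, n_components,
                         seed = s)
    kmeans_cluster(coords, k = k, n_init = n_init, seed = s,
                   compute_metrics = FALSE)$labels
  }
  ref <- run(seeds[1])
  dis <- vapply(seeds[-1], function(s) {
    lab <- run(s)
    1 - matched_agreement(ref, lab, k)
  }, numeric(1))
  list(disagreement = stats::setNames(dis, paste0("seed", seeds[-1])),
       max = max(dis), mean = mean(dis))
}

# Best-case agreement between two labelings over all label permutations.
matched_agreement <- function(a, b, k) {
  if (k > 7) stop("exhaustive matching supported for k <= 7")
  perms <- permutations_of(0:(k - 1))
  best <- 0
  for (p in perms) best <- max(best, mean(p[b + 1] == a))
  best
}

permutations_of <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(permutations_of(v[-i]), function(p) c(v[i], p)))
  out
}
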