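# Clustering algorithms and the three internal validity indices.

test_that("k-means recovers point-mass clusters exactly", {
  centers <- rbind(c(0, 0), c(5, 0), c(0, 5), c(5, 5), c(10, 10))
  x <- centers[rep(1:5, each = 20), ]
  fit <- kmeans_cluster(x, k = 5, seed = 1)
  expect_equal(fit$inertia, 0)
  expect_equal(sort(unique(fit$labels)), 0:4)
  expect_true(all(table(fit$labels) == 20))
  # every point-mass is pure
  for (i in 1:5) {
    rows <- which(rep(1:5, each = 20) == i)
    expect_equal(length(unique(fit$labels[rows])), 1L)
  }
})

test_that("k-means is deterministic given input and seed", {
  blobs <- make_blobs(30, rbind(c(0, 0), c(6, 6), c(-6, 6)), sd = 1, seed = 2)
  f1 <- kmeans_cluster(blobs$x, k = 3, seed = 9)
  f2 <- kmeans_cluster(blobs$x, k = 3, seed = 9)
  expect_identical(f1$labels, f2$labels)
  expect_error(kmeans_cluster(blobs$x[1:3, ], k = 5), "more points")
})

test_that("labels are canonicalized by descending cluster size", {
  set.seed(3)
  x <- rbind(matrix(rnorm(80, 0, 0.3), 40),     # 40 points near (0,0)
             matrix(rnorm(20, 8, 0.3), 10))     # 10 points near (8,8)
  fit <- kmeans_cluster(x, k = 2, seed = 0)
  expect_equal(sum(fit$labels == 0), 40L)
  expect_equal(sum(fit$labels == 1), 10L)
})

test_that("Ward agglomeration merges distant pairs last", {
  x <- rbind(c(0, 0), c(0, 1), c(20, 0), c(20, 1))
  fit <- agglomerative_cluster(x, k = 2, compute_metrics = FALSE)
  expect_equal(fit$labels[1], fit$labels[2])
  expect_equal(fit$labels[3], fit$labels[4])
  expect_false(fit$labels[1] == fit$labels[3])
  # k = N gives singletons
  fitN <- agglomerative_cluster(x, k = 4, compute_metrics = FALSE)
  expect_equal(sort(fitN$labels), 0:3)
})

test_that("Ward agrees with an exhaustive best-merge check on tiny sets", {
  # brute force: for N = 5 points and k = 2, the optimal Ward objective
  # (total within-cluster sum of squares) over all 2-partitions
  set.seed(4)
  for (rep_i in 1:10) {
    x <- matrix(rnorm(10), 5, 2)
    fit <- agglomerative_cluster(x, k = 2, compute_metrics = FALSE)
    wss <- function(lab) {
      sum(sapply(unique(lab), function(cl) {
        xi <- x[lab == cl, , drop = FALSE]
        sum(sweep(xi, 2, colMeans(xi))^2)
      }))
    }
    best <- Inf
    for (code in 1:(2^4)) {                 # all 2-partitions up to symmetry
      lab <- c(0, as.integer(intToBits(code))[1:4])
      if (length(unique(lab)) == 2) best <- min(best, wss(lab))
    }
    # Ward is greedy so it need not be optimal, but on well-behaved draws
    # it should be within a factor; duplicates must never split early
    expect_lte(wss(fit$labels), best * 2 + 1e-9)
  }
  # duplicated rows stay together at k = 2
  xd <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5.2, 5), c(-4, 3))
  fd <- agglomerative_cluster(xd, k = 2, compute_metrics = FALSE)
  expect_equal(fd$labels[1], fd$labels[2])
})

test_that("spectral clustering separates concentric rings where k-means fails", {
  set.seed(5)
  n <- 80
  th <- runif(n, 0, 2 * pi)
  r <- rep(c(1, 6), each = n / 2) + rnorm(n, 0, 0.05)
  x <- cbind(r * cos(th), r * sin(th))
  truth <- rep(0:1, each = n / 2)
  sp <- spectral_cluster(x, k = 2, n_neighbors = 8, seed = 0)
  expect_equal(adjusted_rand_index(sp$labels, truth), 1)
  km <- kmeans_cluster(x, k = 2, seed = 0)
  expect_lt(adjusted_rand_index(km$labels, truth), 0.5)
  # determinism
  sp2 <- spectral_cluster(x, k = 2, n_neighbors = 8, seed = 0)
  expect_identical(sp$labels, sp2$labels)
})

test_that("spectral clustering matches k-means on point-mass clusters", {
  centers <- rbind(c(0, 0), c(9, 0), c(0, 9))
  set.seed(6)
  x <- centers[rep(1:3, each = 15), ] + matrix(rnorm(90, 0, 0.05), 45)
  sp <- spectral_cluster(x, k = 3, n_neighbors = 16, seed = 0)
  km <- kmeans_cluster(x, k = 3, seed = 0)
  expect_equal(adjusted_rand_index(sp$labels, km$labels), 1)
})

test_that("spectral clustering rejects a disconnected neighbor graph", {
  blobs <- make_blobs(20, rbind(c(0, 0), c(100, 100)), sd = 0.1, seed = 7)
  expect_error(spectral_cluster(blobs$x, k = 2, n_neighbors = 3),
               "disconnected")
})

test_that("silhouette matches the hand-computed 1-D case", {
  x <- matrix(c(0, 0.1, 1.0, 1.1), ncol = 1)
  lab <- c(0, 0, 1, 1)
  # by hand: a = 0.1 for every point; b = 1.05, 0.95, 0.95, 1.05
  expected <- mean(c((1.05 - 0.1) / 1.05, (0.95 - 0.1) / 0.95,
                     (0.95 - 0.1) / 0.95, (1.05 - 0.1) / 1.05))
  expect_equal(silhouette_score(x, lab), expected, tolerance = 1e-12)
  # two coincident point-mass clusters at distinct locations: S = 1
  y <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_equal(silhouette_score(y, c(0, 0, 1, 1)), 1)
  expect_error(silhouette_score(x, rep(0, 4)), "2 clusters")
})

test_that("random labels on one blob give silhouette near zero", {
  set.seed(8)
  x <- matrix(rnorm(400), 200, 2)
  lab <- sample(0:1, 200, replace = TRUE)
  expect_lt(abs(silhouette_score(x, lab)), 0.1)
})

test_that("CH index handles degeneracy and ordering of labelings", {
  x <- rbind(matrix(0, 10, 2), matrix(5, 10, 2))
  lab <- rep(0:1, each = 10)
  ch <- calinski_harabasz(x, lab)
  expect_true(is.infinite(ch))
  expect_true(attr(ch, "degenerate"))
  # separated blobs: true labeling beats a corrupted one
  blobs <- make_blobs(25, rbind(c(0, 0), c(8, 8)), sd = 0.6, seed = 9)
  good <- calinski_harabasz(blobs$x, blobs$labels)
  bad_lab <- blobs$labels
  bad_lab[1:12] <- 1 - bad_lab[1:12]
  expect_gt(good, calinski_harabasz(blobs$x, bad_lab))
})

test_that("DB index is zero for point masses and scale invariant", {
  x <- rbind(matrix(0, 10, 2), matrix(5, 10, 2))
  lab <- rep(0:1, each = 10)
  expect_equal(davies_bouldin(x, lab), 0)
  blobs <- make_blobs(20, rbind(c(0, 0), c(6, 1), c(2, 7)), sd = 0.7,
                      seed = 10)
  db1 <- davies_bouldin(blobs$x, blobs$labels)
  db2 <- davies_bouldin(blobs$x * 37.5, blobs$labels)
  expect_equal(db1, db2, tolerance = 1e-12)
  # coincident centroids
  xc <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  dbc <- davies_bouldin(xc, c(0, 0, 1, 1))
  expect_true(is.infinite(dbc))
})

test_that("validity indices agree with brute force on random instances", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    k <- sample(2:4, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    lab <- sample(0:(k - 1), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_score(x, lab), silhouette_bf(x, lab),
                 tolerance = 1e-9)
    expect_equal(calinski_harabasz(x, lab), calinski_harabasz_bf(x, lab),
                 tolerance = 1e-9)
    expect_equal(davies_bouldin(x, lab), davies_bouldin_bf(x, lab),
                 tolerance = 1e-9)
  }
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(12)
  x <- matrix(rnorm(60), 30, 2)
  lab <- sample(0:2, 30, replace = TRUE)
  ours <- silhouette_score(x, lab)
  ref <- mean(cluster::silhouette(lab + 1, dist(x))[, 3])
  expect_equal(ours, ref, tolerance = 1e-9)
})
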