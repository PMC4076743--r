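test_that("PCA reduction matches a covariance eigendecomposition", {
  set.seed(31)
  Y <- matrix(rnorm(6 * 20), 6, 20)  # 6 images, 20 voxels
  red <- pca_reduce(Y, m = 6)
  expect_equal(red$explained_variance_fraction, 1)

  # oracle: eigendecomposition of the voxel-by-voxel feature covariance
  X <- t(Y)
  Xc <- scale(X, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)
  scores <- Xc %*% ev$vectors
  vars <- apply(t(red$values), 2, var)
  expect_true(all(diff(vars) <= 1e-12))
  for (j in seq_len(red$m)) {
    expect_equal(abs(cor(red$values[j, ], scores[, j])), 1,
                 tolerance = 1e-8)
    expect_equal(unname(vars[j]), ev$values[j], tolerance = 1e-8)
  }

  red2 <- pca_reduce(Y, m = 3)
  expect_lt(red2$explained_variance_fraction, 1)
  expect_equal(red2$m, 3)
})

test_that("k-means honors the saturation and single-cluster limits", {
  set.seed(5)
  Y <- matrix(rnorm(4 * 12), 4, 12)
  sat <- kmeans_parcellation(Y, K = 12, seed = 1)
  expect_equal(sat$K, 12)
  expect_equal(sat$inertia, 0)

  one <- kmeans_parcellation(Y, K = 1, seed = 1)
  expect_equal(one$K, 1)
  expect_equal(unname(one$centroids[1, ]), unname(rowMeans(Y)),
               tolerance = 1e-12)
  expect_error(kmeans_parcellation(Y, K = 13), "exceeds")
})

test_that("k-means finds the exhaustive-partition minimum inertia", {
  # 1D separation example
  Y <- matrix(c(0, 0.1, 0.2, 10, 10.1, 10.2), nrow = 1)
  p <- kmeans_parcellation(Y, K = 2, seed = 7)
  expect_equal(p$labels, c(1, 1, 1, 2, 2, 2))

  # random small cases against brute force
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(7 * 2), 7, 2)
    oracle <- best_partition_oracle(X, 2)
    fit <- kmeans_parcellation(t(X), K = 2, seed = seed, n_init = 20)
    expect_equal(fit$inertia, oracle$inertia, tolerance = 1e-10)
    expect_equal(adjusted_rand(fit$labels, oracle$assign), 1)
  }
})

test_that("always exactly K non-empty clusters, even with duplicates", {
  Y <- matrix(rep(c(0, 1), each = 6), nrow = 1)  # heavy duplication
  p <- kmeans_parcellation(Y, K = 4, seed = 2)
  expect_equal(sort(unique(p$labels)), 1:4)
})

test_that("Ward merge cost matches direct substitution", {
  expect_equal(ward_merge_cost(1, 0, 1, 2), 2)
  expect_equal(ward_merge_cost(3, c(1, 1), 3, c(1, 1)), 0)
  expect_equal(ward_merge_cost(2, c(1, 0), 5, c(0, 1)),
               ward_merge_cost(5, c(0, 1), 2, c(1, 0)))
  expect_error(ward_merge_cost(0, 1, 1, 1), "positive")
})

test_that("constrained Ward merges neighbors only and cuts cleanly", {
  # 1 x 4 chain: values (0, 0.1, 5, 5.1) -> {1,2} {3,4}
  Y <- matrix(c(0, 0.1, 5, 5.1), nrow = 1)
  adj <- grid_adjacency(c(1, 4))
  p <- ward_parcellation(Y, adj, K = 2)
  expect_equal(p$labels, c(1, 1, 2, 2))

  tree <- ward_tree(Y, adj)
  expect_equal(cut_ward(tree, 4), 1:4)

  set.seed(41)
  Y2 <- matrix(rnorm(3 * 48), 3, 48)
  adj2 <- grid_adjacency(c(6, 8))
  for (K in c(2, 5, 9)) {
    lab <- ward_parcellation(Y2, adj2, K)$labels
    expect_equal(length(unique(lab)), K)
    expect_true(parcelbench:::labels_are_connected(lab, adj2$edges))
  }
})

test_that("Ward with a complete graph reproduces unconstrained Ward", {
  set.seed(17)
  n <- 25
  X <- matrix(rnorm(n * 3), n, 3)
  full_edges <- t(combn(n, 2))
  adj <- structure(list(edges = full_edges, n_vertices = n,
                        coords = X, dims = n),
                   class = "parcel_adjacency")
  hc <- hclust(dist(X), method = "ward.D2")
  for (K in c(2, 4, 7)) {
    mine <- ward_parcellation(t(X), adj, K)$labels
    ref <- cutree(hc, K)
    expect_equal(adjusted_rand(mine, ref), 1)
  }
})

test_that("Ward errors when K is below the component count", {
  mask <- matrix(TRUE, 1, 5)
  mask[1, 3] <- FALSE  # two disconnected segments
  adj <- grid_adjacency(mask = mask)
  Y <- matrix(rnorm(4), 1, 4)
  tree <- ward_tree(Y, adj)
  expect_equal(tree$n_components, 2)
  expect_error(cut_ward(tree, 1), "connected components")
  expect_equal(length(unique(cut_ward(tree, 2))), 2)
})

test_that("geometric clustering ignores the signal", {
  cfg <- simulation_config(grid_shape = c(8, 8), K_true = 3)
  a <- simulate_parcel_dataset(cfg, seed = 1)
  b <- simulate_parcel_dataset(cfg, seed = 99)
  pa <- geometric_parcellation(a$signal, K = 4, seed = 5)
  pb <- geometric_parcellation(b$signal, K = 4, seed = 5)
  expect_identical(pa$labels, pb$labels)

  expect_equal(geometric_parcellation(a$signal, K = 1, seed = 1)$K, 1)
})

test_that("geometric k-means on a 4x4 grid recovers the four quadrants", {
  coords <- arrayInd(1:16, c(4, 4))
  p <- geometric_parcellation(coords, K = 4, seed = 3, n_init = 50)
  quadrant <- paste(coords[, 1] <= 2, coords[, 2] <= 2)
  expect_equal(adjusted_rand(p$labels, as.integer(factor(quadrant))), 1)
})
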