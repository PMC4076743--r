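test_that("ARI and AMI equal 1 on identical labelings and are
           permutation invariant", {
  set.seed(61)
  u <- random_labeling(60, 4)
  expect_equal(adjusted_rand(u, u), 1)
  expect_equal(adjusted_mutual_info(u, u), 1)
  perm <- c(3, 4, 1, 2)[u]
  expect_equal(adjusted_rand(u, perm), 1)
  expect_equal(adjusted_mutual_info(u, perm), 1)
  expect_error(adjusted_rand(u, u[-1]), "equal length")
  expect_error(adjusted_mutual_info(u, u[-1]), "equal length")
})

test_that("ARI matches the hand-computed contingency value and the
           mclust implementation", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  skip_if_not_installed("mclust")
  set.seed(62)
  for (i in 1:20) {
    u1 <- random_labeling(50, sample(2:6, 1))
    u2 <- random_labeling(50, sample(2:6, 1))
    expect_equal(adjusted_rand(u1, u2),
                 mclust::adjustedRandIndex(u1, u2), tolerance = 1e-10)
    expect_equal(adjusted_rand(u1, u2), ari_oracle(u1, u2),
                 tolerance = 1e-10)
    # symmetry
    expect_equal(adjusted_mutual_info(u1, u2),
                 adjusted_mutual_info(u2, u1), tolerance = 1e-12)
  }
})

test_that("AMI reproduces reference values from an independent
           implementation", {
  # frozen oracle values (scikit-learn, max normalization)
  expect_equal(adjusted_mutual_info(c(1, 1, 2, 2, 3, 3),
                                    c(1, 1, 1, 2, 2, 2)),
               0.225042283198, tolerance = 1e-9)
  expect_equal(adjusted_mutual_info(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               -0.5, tolerance = 1e-9)
  expect_equal(adjusted_mutual_info(c(1, 2, 3, 4, 1, 2, 3, 4),
                                    c(1, 1, 2, 2, 3, 3, 4, 4)),
               -0.166666666667, tolerance = 1e-9)
  expect_equal(adjusted_mutual_info(c(1, 1, 1, 2, 2, 3),
                                    c(2, 2, 1, 1, 3, 3)),
               0.077596261768, tolerance = 1e-9)
  u <- c(1, 4, 3, 2, 2, 4, 1, 3, 1, 1, 3, 4, 3, 4, 3, 4, 3, 1, 4, 2, 3,
         2, 1, 4, 4, 3, 2, 4, 3, 2, 2, 1, 1, 3, 4, 1, 4, 4, 2, 3)
  v <- c(1, 3, 3, 2, 1, 3, 2, 3, 3, 3, 3, 1, 2, 2, 2, 1, 2, 1, 3, 3, 3,
         3, 2, 3, 2, 1, 3, 2, 1, 2, 3, 1, 2, 1, 3, 2, 1, 1, 2, 3)
  expect_equal(adjusted_mutual_info(u, v), -0.037154893101,
               tolerance = 1e-9)
  expect_equal(adjusted_rand(u, v), -0.037777688183, tolerance = 1e-9)
})

test_that("both metrics handle trivial partitions", {
  expect_equal(adjusted_mutual_info(rep(1, 10), rep(2, 10)), 1)
  expect_equal(adjusted_rand(rep(1, 10), rep(1, 10)), 1)
})

test_that("independent labelings score near zero on average", {
  set.seed(63)
  scores_ami <- replicate(15, {
    adjusted_mutual_info(random_labeling(2000, 8),
                         random_labeling(2000, 8))
  })
  scores_ari <- replicate(15, {
    adjusted_rand(random_labeling(2000, 8), random_labeling(2000, 8))
  })
  expect_lt(abs(mean(scores_ami)), 0.01)
  expect_lt(abs(mean(scores_ari)), 0.01)
})

test_that("bootstrap reproducibility of the geometric method is exact", {
  cfg <- simulation_config(grid_shape = c(8, 8), K_true = 3,
                           n_subjects = 6)
  ds <- simulate_parcel_dataset(cfg, seed = 64)
  st <- bootstrap_reproducibility(ds$signal, "geometric", K = 4, B = 4,
                                  seed = 1)
  expect_equal(st$pairwise_scores, rep(1, 6))
  expect_equal(st$mean_score, 1)

  two <- bootstrap_reproducibility(ds$signal, "ward", K = 3, B = 2,
                                   seed = 2)
  expect_length(two$pairwise_scores, 1)
  expect_equal(two$mean_score, two$pairwise_scores)
  expect_error(bootstrap_reproducibility(ds$signal, "ward", 3, B = 1),
               "at least 2")
})

test_that("chance correction gives near-zero scores for random
           labelers", {
  set.seed(65)
  labelings <- replicate(8, random_labeling(1500, 5), simplify = FALSE)
  scores <- parcelbench:::pairwise_agreement(labelings, "ami")
  expect_lt(abs(mean(scores)), 0.01)
})

test_that("bootstrap estimates are deterministic given the seed", {
  cfg <- simulation_config(grid_shape = c(6, 6), K_true = 2,
                           n_subjects = 5)
  ds <- simulate_parcel_dataset(cfg, seed = 66)
  a <- bootstrap_reproducibility(ds$signal, "ward", 3, B = 3, seed = 9)
  b <- bootstrap_reproducibility(ds$signal, "ward", 3, B = 3, seed = 9)
  expect_identical(a$pairwise_scores, b$pairwise_scores)
})

test_that("bootstrap ARI reproducibility of Ward parcellations declines
           with the number of parcels (conservative selection)", {
  adj <- grid_adjacency(c(20, 25))
  Ks <- c(2L, 10L, 30L)
  curves <- vapply(1:2, function(r) {
    ds <- simulate_parcel_dataset(
      simulation_config(jitter = 1, fwhm = 1.17), seed = 600 + r)
    boots <- parcelbench:::bootstrap_labelings(ds$signal, "ward", Ks, 6,
                                               adj, seed = 700 + r)
    vapply(seq_along(Ks), function(ki) {
      mean(parcelbench:::pairwise_agreement(lapply(boots, `[[`, ki),
                                            "ari"))
    }, numeric(1))
  }, numeric(3))
  curve <- rowMeans(curves)
  expect_gt(curve[1], curve[2])
  expect_gt(curve[2], curve[3])
})
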