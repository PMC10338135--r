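test_that("AUC matches hand counts, extremes and the pROC oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4), c(1, 0, 1)), 0.5)  # 1 win, 1 loss
  expect_error(roc_auc(1:3, c(1, 1, 1)), "two distinct")

  set.seed(51)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    scores <- round(rnorm(n), 1)  # rounding forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and flips with sign", {
  set.seed(53)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.5)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a, tolerance = 1e-12)
  expect_equal(roc_auc(qlogis(plogis(scores)), labels), a, tolerance = 1e-9)
  expect_equal(roc_auc(-scores, labels), 1 - a, tolerance = 1e-12)  # tie-free
})

test_that("ARI matches examples, label permutation and the mclust oracle", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  # pair-counting by hand over the 6 pairs of [0,0,1,1] vs [0,1,0,1]:
  # sum_ij C(n_ij,2) = 0, expected = 2*2/6, max = 2 -> (0 - 2/3)/(2 - 2/3)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)),
               (0 - 2 / 3) / (2 - 2 / 3), tolerance = 1e-12)
  expect_error(adjusted_rand_index(1:4, 1:5), "length")

  set.seed(57)
  for (rep in 1:20) {
    n <- sample(20:80, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("ARI of independent random partitions concentrates near zero", {
  set.seed(59)
  aris <- replicate(50, {
    adjusted_rand_index(sample(1:5, 1000, replace = TRUE),
                        sample(1:5, 1000, replace = TRUE))
  })
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("ternary mean test agrees with a permutation oracle near the boundary", {
  expect_identical(mean_difference_test(rep(0.9, 10), rep(0.9, 10))$verdict,
                   "tie")
  set.seed(61)
  a <- 0.95 + rnorm(50, sd = 1e-4)
  b <- 0.80 + rnorm(50, sd = 1e-4)
  expect_identical(mean_difference_test(a, b)$verdict, "A_wins")
  expect_identical(mean_difference_test(b, a)$verdict, "B_wins")
  expect_error(mean_difference_test(1, 2), "at least 2")

  # borderline cases: verdict must match a 10k-shuffle permutation test
  perm_verdict <- function(a, b, alpha = 0.05, nperm = 10000) {
    obs <- mean(a) - mean(b)
    pool <- c(a, b)
    n <- length(a)
    perm <- replicate(nperm, {
      idx <- sample(length(pool), n)
      mean(pool[idx]) - mean(pool[-idx])
    })
    p <- (1 + sum(abs(perm) >= abs(obs))) / (nperm + 1)
    if (p >= alpha) "tie" else if (obs > 0) "A_wins" else "B_wins"
  }
  for (delta in c(0.002, 0.02)) {
    a <- 0.85 + rnorm(30, sd = 0.02)
    b <- 0.85 - delta + rnorm(30, sd = 0.02)
    expect_identical(mean_difference_test(a, b)$verdict, perm_verdict(a, b))
  }
})

test_that("resampled classification separates the benchmark preset", {
  mats <- make_preset_matrices(seed = 71, specs = list(mer_spec(2, 2)),
                               n_per_class = 60, length = 1000)
  rep1 <- resample_classify(mats[[1]], n_resamples = 5, per_class = 50,
                            classifier = "knn", seed = 72,
                            feature_name = "(2,2)-mer")
  expect_gt(rep1$mean, 0.9)
  expect_equal(rep1$mean, mean(rep1$per_resample_metric), tolerance = 1e-12)
  expect_true(rep1$ci95[1] <= rep1$mean && rep1$mean <= rep1$ci95[2])

  # identical seed -> identical report
  rep2 <- resample_classify(mats[[1]], n_resamples = 5, per_class = 50,
                            classifier = "knn", seed = 72,
                            feature_name = "(2,2)-mer")
  expect_identical(rep1$per_resample_metric, rep2$per_resample_metric)
})

test_that("all registry classifiers run and beat chance on separated data", {
  mats <- make_preset_matrices(seed = 73, specs = list(mer_spec(1, 1)),
                               n_per_class = 40, length = 1000,
                               epsilon = 0.4)
  for (clf in c("knn", "logistic", "rf")) {
    rp <- resample_classify(mats[[1]], n_resamples = 2, per_class = 40,
                            classifier = clf, folds = 5, repeats = 1,
                            seed = 74)
    expect_gt(rp$mean, 0.8)
  }
  expect_error(resample_classify(mats[[1]], classifier = "svm"))
})

test_that("a null dataset yields chance-level AUC", {
  ma <- random_transition_model(2, seed = 81)
  recs <- make_two_class_dataset(ma, ma, 60, 500, seed = 82)
  fm <- build_feature_matrix(recs, mer_spec(1, 1))
  rp <- resample_classify(fm, n_resamples = 5, per_class = 50,
                          classifier = "knn", seed = 83)
  expect_gt(rp$mean, 0.4)
  expect_lt(rp$mean, 0.6)
})

test_that("clustering recovers widely separated classes and is seeded", {
  mats <- make_preset_matrices(seed = 91, specs = list(mer_spec(2, 2)),
                               n_per_class = 50, length = 1000,
                               epsilon = 0.5)
  res <- cluster_eval(mats[[1]], algorithm = "kmeans", replicates = 3,
                      seed = 92)
  expect_gt(res$mean_ari, 0.8)
  res2 <- cluster_eval(mats[[1]], algorithm = "kmeans", replicates = 3,
                       seed = 92)
  expect_identical(res$per_replicate_ari, res2$per_replicate_ari)

  agg <- cluster_eval(mats[[1]], algorithm = "agglomerative", seed = 93)
  expect_gt(agg$mean_ari, 0.8)

  # degenerate single-class, single-cluster case scores 1
  one <- mats[[1]][mats[[1]]$class == "A", ]
  expect_equal(cluster_eval(one, algorithm = "kmeans",
                            n_clusters = 1)$mean_ari, 1)
  expect_error(cluster_eval(mats[[1]], algorithm = "dbscan"))
})
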