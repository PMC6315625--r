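test_that("accuracy matches the spec'd worked examples and is permutation-invariant", {
  expect_equal(clustering_accuracy(c(1, 1, 2), c(2, 2, 1)), 1)
  expect_equal(clustering_accuracy(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0.5)
  expect_equal(clustering_accuracy(c("a", "b", "a"), c("a", "b", "a")), 1)
  expect_error(clustering_accuracy(1:3, 1:4), "equal length")
})

test_that("accuracy equals exhaustive permutation enumeration on random labelings", {
  set.seed(19)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    truth <- sample(1:sample(2:4, 1), n, replace = TRUE)
    pred <- sample(1:sample(2:4, 1), n, replace = TRUE)
    expect_equal(clustering_accuracy(truth, pred),
                 oracle_accuracy(truth, pred))
  }
})

test_that("the assignment solver matches brute-force permutation search", {
  set.seed(29)
  for (i in 1:30) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n, -10, 10), n, n)
    perm <- gmvnmf:::solve_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), perm)]),
                 oracle_assignment_cost(cost), tolerance = 1e-12)
  }
})

test_that("pairwise metrics match the worked examples and pair enumeration", {
  got <- pairwise_metrics(c(1, 1, 2, 2), c(1, 1, 1, 2))
  expect_equal(unname(got), c(0.5, 1 / 3, 0.4))
  expect_equal(unname(pairwise_metrics(1:4, c(2, 1, 4, 3))), c(0, 0, 0))
  expect_equal(unname(pairwise_metrics(c(1, 1, 2, 2), c(1, 1, 1, 1))),
               c(1, 1 / 3, 0.5))
  set.seed(37)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    truth <- sample(1:3, n, replace = TRUE)
    pred <- sample(1:3, n, replace = TRUE)
    expect_equal(pairwise_metrics(truth, pred), oracle_pairwise(truth, pred))
  }
})

test_that("pair counts satisfy the contingency conservation identities", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    truth <- sample(1:3, n, replace = TRUE)
    pred <- sample(1:4, n, replace = TRUE)
    tab <- table(truth, pred)
    tp <- sum(choose(tab, 2))
    expect_equal(tp + (sum(choose(rowSums(tab), 2)) - tp),
                 sum(choose(rowSums(tab), 2)))
    # harmonic-mean identity whenever both parts are positive
    pm <- pairwise_metrics(truth, pred)
    if (pm["recall"] > 0 && pm["precision"] > 0) {
      expect_equal(1 / pm[["f_measure"]],
                   (1 / pm[["recall"]] + 1 / pm[["precision"]]) / 2)
    }
  }
})

test_that("metrics are invariant to relabeling either side", {
  set.seed(43)
  truth <- sample(1:3, 20, replace = TRUE)
  pred <- sample(1:3, 20, replace = TRUE)
  relab <- c(7, 5, 9)
  expect_equal(clustering_accuracy(truth, pred),
               clustering_accuracy(relab[truth], pred))
  expect_equal(pairwise_metrics(truth, pred),
               pairwise_metrics(truth, relab[pred]))
})

test_that("cluster_basis separates point masses, is deterministic, and validates", {
  set.seed(53)
  W <- rbind(matrix(rnorm(20, mean = 0, sd = 0.05), 10, 2),
             matrix(rnorm(20, mean = 5, sd = 0.05), 10, 2))
  lab <- cluster_basis(W, 2, seed = 1)
  expect_equal(clustering_accuracy(rep(1:2, each = 10), lab), 1)
  expect_identical(lab, cluster_basis(W, 2, seed = 1))

  # n_clusters = n puts every sample in its own cluster (zero WCSS)
  Wd <- matrix(seq_len(12), 6, 2)
  expect_equal(sort(unique(cluster_basis(Wd, 6, seed = 1))), 1:6)
  expect_error(cluster_basis(Wd, 7), "exceeds")
})

test_that("clustering_report assembles all four metrics consistently", {
  truth <- c(1, 1, 2, 2)
  pred <- c(1, 1, 1, 2)
  rep <- clustering_report(truth, pred)
  expect_equal(rep$ac, 0.75)
  expect_equal(rep$recall, 0.5)
  expect_equal(rep$precision, 1 / 3)
  expect_equal(rep$f_measure, 0.4)
})

test_that("evaluate_clustering reports per-repeat rows with mean and variance", {
  gt <- generate_factor_model(synthetic_spec(n_samples = 30, n_features = 40,
                                             n_views = 2, n_diff_genes = 10,
                                             seed = 3))
  cfg <- solver_config(k = 3, r = 2, seed = 1, max_iter = 30)
  tab <- evaluate_clustering("jnmf", gt$dataset, cfg, gt$truth$labels,
                             repeats = 3, n_restarts = 5)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$ac >= 0 & tab$ac <= 1))
  expect_length(attr(tab, "mean"), 4)
  expect_length(attr(tab, "var"), 4)
})
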