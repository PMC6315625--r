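# Solver unit and property tests. The deeper cross-model suites (bitwise
# reductions over many seeds, 50-problem monotonicity, recovery at scale)
# live in test-acceptance.R; these cover each operation's contract quickly.

test_that("objective_gmvnmf matches elementwise and trace-expansion oracles", {
  set.seed(5)
  for (i in 1:10) {
    n <- 4; m <- 3; d <- 2; k <- 3; r <- 2
    X <- lapply(1:d, function(I) matrix(runif(n * m), n, m))
    W <- matrix(runif(n * k), n, k)
    U <- lapply(1:d, function(I) matrix(runif(k * r), k, r))
    V <- matrix(runif(r * m), r, m)
    graphs <- lapply(1:d, function(I) knn_adjacency(matrix(runif(n * 2), n, 2), 2))
    L <- lapply(graphs, `[[`, "L")
    lam <- runif(1, 0, 3)
    got <- objective_gmvnmf(X, graphs, W, U, V, lam)
    expect_equal(got, oracle_objective_gmvnmf(X, L, W, U, V, lam),
                 tolerance = 1e-10)
    expect_equal(got, trace_objective_gmvnmf(X, L, W, U, V, lam),
                 tolerance = 1e-8)
  }
  # exact factorization with lambda = 0 scores exactly zero
  p <- planted_problem(1)
  expect_equal(objective_gmvnmf(p$X, NULL, p$W, p$U, p$V, 0), 0)
})

test_that("gmvnmf_fit with all lambdas zero matches mvnmf_fit iterate-for-iterate", {
  gt <- generate_factor_model(synthetic_spec(n_samples = 25, n_features = 30,
                                             n_views = 2, n_diff_genes = 10,
                                             seed = 4))
  graphs <- lapply(gt$dataset$views, knn_adjacency, K = 4)
  cfg <- solver_config(k = 3, r = 2, lambdas = 0, seed = 9, max_iter = 25, tol = 0)
  fg <- gmvnmf_fit(gt$dataset, graphs, cfg)
  fm <- mvnmf_fit(gt$dataset, cfg)
  expect_identical(fg$objective_history, fm$objective_history)
  expect_identical(fg$W, fm$W)
  expect_identical(fg$V, fm$V)
})

test_that("planted noise-free data is recovered to near-zero residual", {
  p <- planted_problem(17, n = 30, m = 40, d = 2, k = 3, r = 2)
  cfg <- solver_config(k = 3, r = 2, seed = 2, max_iter = 500, tol = 0)
  fit <- mvnmf_fit(p$X, cfg)
  expect_lt(tail(fit$objective_history, 1), 1e-3 * fit$objective_history[1])
})

test_that("solver contracts: determinism, non-negativity, dimension errors", {
  X <- random_views(31, n = 12, m = 10, d = 2)
  cfg <- solver_config(k = 4, r = 2, seed = 5, max_iter = 20, tol = 0)
  f1 <- mvnmf_fit(X, cfg)
  f2 <- mvnmf_fit(X, cfg)
  expect_identical(f1$objective_history, f2$objective_history)
  for (fitter in list(mvnmf_fit, jnmf_fit,
                      function(x, c) inmf_fit(x, c),
                      function(x, c) ionmf_fit(x, c))) {
    f <- fitter(X, cfg)
    expect_true(all(f$W >= 0))
    for (nm in intersect(c("U_list", "H_list", "V_list"), names(f))) {
      expect_true(all(sapply(f[[nm]], min) >= 0))
    }
    expect_true(all(is.finite(f$objective_history)))
  }
  Xneg <- X; Xneg[[1]][1, 1] <- -1
  expect_error(mvnmf_fit(Xneg, cfg), "non-negative")
  expect_error(mvnmf_fit(X, solver_config(k = 4, r = 4, seed = 1)), "k - 1")
  expect_error(mvnmf_fit(X, solver_config(k = 40, r = 2, seed = 1)), "exceeds")
})

test_that("zero data collapses the residual objective immediately", {
  X <- list(matrix(0, 6, 8), matrix(0, 6, 8))
  cfg <- solver_config(k = 3, r = 2, seed = 1, max_iter = 5, tol = 0)
  fit <- suppressWarnings(mvnmf_fit(X, cfg))
  # history[1] is the objective at initialization; one update zeroes it
  expect_gt(fit$objective_history[1], 0)
  expect_equal(fit$objective_history[2], 0)
})

test_that("jNMF with d = 1 reproduces classical two-factor NMF bitwise", {
  set.seed(77)
  X <- matrix(runif(15 * 12), 15, 12)
  cfg <- solver_config(k = 4, seed = 13, max_iter = 30, tol = 0)
  fj <- jnmf_fit(list(X), cfg)
  ref <- reference_nmf(X, 4, seed = 13, max_iter = 30)
  expect_identical(fj$objective_history, ref$history)
  expect_identical(fj$W, ref$W)
  expect_identical(fj$H_list[[1]], ref$H)
})

test_that("iNMF reduces to jNMF at lambda = 0 with zero heterogeneous terms", {
  X <- random_views(8, n = 14, m = 11, d = 3)
  cfg <- solver_config(k = 3, seed = 21, max_iter = 25, tol = 0, lambda_inmf = 0)
  fi <- inmf_fit(X, cfg, v_init = "zero")
  fj <- jnmf_fit(X, cfg)
  expect_identical(fi$objective_history, fj$objective_history)
  expect_identical(fi$W, fj$W)
  expect_true(all(sapply(fi$V_list, function(v) all(v == 0))))
})

test_that("a large iNMF penalty shrinks the heterogeneous contribution", {
  X <- random_views(9, n = 20, m = 15, d = 2)
  ratio <- function(lam) {
    cfg <- solver_config(k = 3, seed = 3, max_iter = 80, tol = 0,
                         lambda_inmf = lam)
    f <- inmf_fit(X, cfg)
    het <- sum(sapply(1:2, function(I) sum((f$V_list[[I]] %*% f$H_list[[I]])^2)))
    hom <- sum(sapply(1:2, function(I) sum((f$W %*% f$H_list[[I]])^2)))
    het / hom
  }
  expect_lt(ratio(1e6), 1e-3)
  expect_lt(ratio(1e6), ratio(0))
})

test_that("iONMF reduces to jNMF at alpha = 0 and large alpha improves orthogonality", {
  X <- random_views(10, n = 16, m = 13, d = 2)
  cfg0 <- solver_config(k = 3, seed = 6, max_iter = 25, tol = 0, alpha = 0)
  expect_identical(ionmf_fit(X, cfg0)$objective_history,
                   jnmf_fit(X, cfg0)$objective_history)
  ortho_err <- function(alpha) {
    cfg <- solver_config(k = 3, seed = 6, max_iter = 100, tol = 0, alpha = alpha)
    f <- ionmf_fit(X, cfg)
    sum(sapply(f$H_list, function(H) sum((tcrossprod(H) - diag(3))^2)))
  }
  expect_lt(ortho_err(10), ortho_err(0))
})

test_that("objectives are non-increasing for every model on random data", {
  for (s in 1:5) {
    X <- random_views(100 + s, n = 15, m = 18, d = 2)
    cfg <- solver_config(k = 4, r = 3, lambdas = 2, lambda_inmf = 0.5,
                         alpha = 0.5, seed = s, max_iter = 60, tol = 0)
    graphs <- lapply(X, knn_adjacency, K = 3)
    expect_lt(max_rel_increase(jnmf_fit(X, cfg)$objective_history), 1e-9)
    expect_lt(max_rel_increase(mvnmf_fit(X, cfg)$objective_history), 1e-9)
    expect_lt(max_rel_increase(gmvnmf_fit(X, graphs, cfg)$objective_history), 1e-7)
    expect_lt(max_rel_increase(inmf_fit(X, cfg)$objective_history), 1e-7)
    expect_lt(max_rel_increase(ionmf_fit(X, cfg)$objective_history), 1e-7)
  }
})

test_that("scaling the data by c scales the converged residual by c^2", {
  p <- planted_problem(41, n = 20, m = 24, d = 2, k = 3, r = 2)
  X1 <- lapply(p$X, function(x) x + 0.05)  # keep away from the exact optimum
  X3 <- lapply(X1, function(x) 3 * x)
  cfg <- solver_config(k = 3, r = 2, seed = 7, max_iter = 400, tol = 0)
  f1 <- mvnmf_fit(X1, cfg)
  f3 <- mvnmf_fit(X3, cfg)
  expect_equal(tail(f3$objective_history, 1),
               9 * tail(f1$objective_history, 1), tolerance = 1e-3)
})

test_that("the literal Laplacian denominator is available behind its flag", {
  gt <- generate_factor_model(synthetic_spec(n_samples = 20, n_features = 25,
                                             n_views = 2, n_diff_genes = 10,
                                             seed = 2))
  graphs <- lapply(gt$dataset$views, knn_adjacency, K = 3)
  cfg <- solver_config(k = 3, r = 2, lambdas = 1, seed = 3, max_iter = 10,
                       tol = 0, laplacian_update = "literal")
  cfg_split <- solver_config(k = 3, r = 2, lambdas = 1, seed = 3, max_iter = 10,
                             tol = 0)
  flit <- gmvnmf_fit(gt$dataset, graphs, cfg)
  fsplit <- gmvnmf_fit(gt$dataset, graphs, cfg_split)
  expect_false(identical(flit$objective_history, fsplit$objective_history))
  expect_true(all(fsplit$W >= 0))
})

test_that("grid_search evaluates only admissible points and finds the planted optimum", {
  gt <- generate_factor_model(synthetic_spec(n_samples = 45, n_features = 60,
                                             n_views = 2, seed = 12))
  graphs <- lapply(gt$dataset$views, knn_adjacency, K = 5)
  labels <- gt$truth$labels
  score_fn <- function(fit) {
    clustering_accuracy(labels, cluster_basis(fit$W, 3, seed = 1, n_restarts = 5))
  }
  base <- solver_config(k = 4, seed = 5, max_iter = 60, tol = 0)
  gs <- grid_search(gt$dataset, graphs, k_values = c(2, 3), r_values = c(1, 2, 3),
                    lambda_values = c(0, 100), score_fn, base_config = base)
  expect_true(all(gs$table$r <= gs$table$k - 1))
  # the planted configuration attains the maximum (ties allowed)
  planted_rows <- gs$table$k == 3 & gs$table$r == 2
  expect_equal(max(gs$table$score[planted_rows]), max(gs$table$score))
  expect_equal(gs$best_score, max(gs$table$score))

  # single-point grid returns that point
  gs1 <- grid_search(gt$dataset, graphs, k_values = 3, r_values = 2,
                     lambda_values = 100, score_fn, base_config = base)
  expect_equal(nrow(gs1$table), 1)
  expect_equal(gs1$best_config$k, 3L)
  expect_error(grid_search(gt$dataset, graphs, k_values = 2, r_values = 5,
                           lambda_values = 0, score_fn, base_config = base),
               "empty")
})

test_that("factorization results round-trip bit-exactly through text files", {
  X <- random_views(55, n = 10, m = 8, d = 2)
  cfg <- solver_config(k = 3, r = 2, seed = 1, max_iter = 15, tol = 0)
  fit <- mvnmf_fit(X, cfg)
  dir <- file.path(tempdir(), "fit_roundtrip")
  write_result(fit, dir)
  back <- read_result(dir)
  expect_identical(unname(back$W), unname(fit$W))
  expect_identical(unname(back$V), unname(fit$V))
  expect_identical(unname(back$U_list[[2]]), unname(fit$U_list[[2]]))
  expect_identical(back$objective_history, fit$objective_history)
})
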