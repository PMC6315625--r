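## Multiplicative-update solvers for the five integrative NMF models:
##
##   jNMF    min sum_I ||X_I - W H_I||_F^2
##   iNMF    min sum_I ||X_I - (W + V_I) H_I||_F^2 + lambda sum_I ||V_I H_I||_F^2
##   iONMF   min sum_I ||X_I - W H_I||_F^2 + alpha ||H_I H_I' - Id||_F^2
##   MvNMF   min sum_I ||X_I - W U_I V||_F^2
##   GMvNMF  min sum_I ||X_I - W U_I V||_F^2 + lambda_I tr(W' L_I W)
##
## All factors are non-negative; each update rescales a factor by a ratio of
## non-negative terms, so non-negativity is preserved automatically.

#' Solver configuration
#'
#' Collects the hyper-parameters of the factorization models. `k` is the
#' width of the shared basis (the degree of dimensionality reduction); `r`
#' the rank of the shared coefficient space, constrained to `1 <= r <= k - 1`
#' for the shared-coefficient models; `lambdas` the per-view graph
#' regularization weights (a scalar is recycled across views, matching the
#' convention of setting all views' weights equal); `lambda_inmf` the
#' heterogeneity penalty of the integrative model; `alpha` the orthogonality
#' penalty.
#'
#' @param k Inner dimension of the shared basis `W` (n x k).
#' @param r Rank of the shared coefficient matrix `V` (r x m); only used by
#'   the shared-coefficient models. Default `max(1, k - 1)`.
#' @param lambdas Non-negative graph regularization weight(s), one per view
#'   or a scalar.
#' @param lambda_inmf Non-negative heterogeneity penalty weight.
#' @param alpha Non-negative orthogonality penalty weight.
#' @param max_iter Maximum number of multiplicative update sweeps.
#' @param tol Relative objective-change threshold for convergence.
#' @param seed Integer seed controlling the random factor initialization.
#' @param eps Small positive constant added to every update denominator to
#'   avoid division by zero on sparse iterates.
#' @param laplacian_update `"split"` (default) moves the adjacency part of
#'   the Laplacian to the update numerator, guaranteeing non-negative
#'   iterates; `"literal"` keeps `lambda * L W` wholly in the denominator,
#'   which can produce negative entries and is provided for fidelity
#'   experiments only.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(k, r = max(1L, k - 1L), lambdas = 0,
                          lambda_inmf = 0, alpha = 0,
                          max_iter = 100L, tol = 1e-5, seed = 1L,
                          eps = 1e-10,
                          laplacian_update = c("split", "literal")) {
  k <- assert_count(k, "k")
  r <- assert_count(r, "r")
  max_iter <- assert_count(max_iter, "max_iter")
  if (any(lambdas < 0) || lambda_inmf < 0 || alpha < 0) {
    stop2("penalty weights must be non-negative")
  }
  if (tol < 0) stop2("`tol` must be non-negative")
  if (eps <= 0) stop2("`eps` must be positive")
  structure(list(k = k, r = r, lambdas = lambdas, lambda_inmf = lambda_inmf,
                 alpha = alpha, max_iter = max_iter, tol = tol,
                 seed = as.integer(seed), eps = eps,
                 laplacian_update = match.arg(laplacian_update)),
            class = "solver_config")
}

as_views <- function(data) {
  if (inherits(data, "multiview_dataset")) return(data$views)
  if (is.matrix(data)) return(list(view1 = data))
  if (is.list(data)) return(data)
  stop2("`data` must be a multiview_dataset, a matrix, or a list of matrices")
}

check_views <- function(X) {
  for (i in seq_along(X)) assert_nonneg(X[[i]], sprintf("X[[%d]]", i))
  dims <- lapply(X, dim)
  if (length(unique(dims)) != 1) stop2("all views must share dimensions")
  X
}

new_result <- function(model, history, converged, config, ...) {
  structure(c(list(model = model,
                   objective_history = history,
                   converged = converged,
                   # history[1] is the objective at initialization
                   n_iter = length(history) - 1L,
                   config = config),
              list(...)),
            class = "factorization_result")
}

#' @export
print.factorization_result <- function(x, ...) {
  cat(sprintf("<factorization_result> model = %s, %d iteration(s), %s\n",
              x$model, x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  cat(sprintf("  final objective: %.6g\n", utils::tail(x$objective_history, 1)))
  invisible(x)
}

rel_change <- function(prev, cur, eps) abs(prev - cur) / max(abs(prev), eps)

## ---------------------------------------------------------------------------
## Objective functions
## ---------------------------------------------------------------------------

frob2 <- function(x) sum(x * x)

#' Objective value of the graph-regularized shared-coefficient model
#'
#' `sum_I ||X_I - W U_I V||_F^2 + sum_I lambda_I tr(W' L_I W)`. With all
#' `lambdas` zero this is the plain shared-coefficient (MvNMF) objective.
#'
#' @param data A [multiview_dataset()] or list of matrices.
#' @param graphs List of [knn_adjacency()] graphs, one per view (may be
#'   `NULL` when all `lambdas` are zero).
#' @param W,U_list,V The factors: `W` is n x k, each `U_list[[I]]` k x r,
#'   `V` r x m.
#' @param lambdas Per-view regularization weights (scalar recycled).
#' @return A non-negative scalar.
#' @export
objective_gmvnmf <- function(data, graphs = NULL, W, U_list, V, lambdas = 0) {
  X <- check_views(as_views(data))
  d <- length(X)
  lambdas <- rep_len(lambdas, d)
  if (ncol(W) != nrow(U_list[[1]]) || ncol(U_list[[1]]) != nrow(V) ||
      nrow(W) != nrow(X[[1]]) || ncol(V) != ncol(X[[1]])) {
    stop2("factor dimensions are inconsistent with the data")
  }
  val <- 0
  for (I in seq_len(d)) {
    val <- val + frob2(X[[I]] - W %*% U_list[[I]] %*% V)
    if (lambdas[I] > 0) {
      if (is.null(graphs)) stop2("graphs required when lambdas > 0")
      val <- val + lambdas[I] * laplacian_quadratic(graphs[[I]], W)
    }
  }
  val
}

#' Objective value of the joint model: `sum_I ||X_I - W H_I||_F^2`
#' @inheritParams objective_gmvnmf
#' @param H_list List of k x m coefficient matrices, one per view.
#' @return A non-negative scalar.
#' @export
objective_jnmf <- function(data, W, H_list) {
  X <- check_views(as_views(data))
  sum(vapply(seq_along(X),
             function(I) frob2(X[[I]] - W %*% H_list[[I]]), numeric(1)))
}

#' Objective value of the integrative model with heterogeneous terms
#' @inheritParams objective_jnmf
#' @param V_list Per-view heterogeneous basis matrices (n x k).
#' @param lambda Heterogeneity penalty weight.
#' @return A non-negative scalar.
#' @export
objective_inmf <- function(data, W, H_list, V_list, lambda) {
  X <- check_views(as_views(data))
  resid <- sum(vapply(seq_along(X), function(I) {
    frob2(X[[I]] - (W + V_list[[I]]) %*% H_list[[I]])
  }, numeric(1)))
  pen <- sum(vapply(seq_along(X), function(I) {
    frob2(V_list[[I]] %*% H_list[[I]])
  }, numeric(1)))
  resid + lambda * pen
}

#' Objective value of the orthogonality-regularized joint model
#' @inheritParams objective_jnmf
#' @param alpha Orthogonality penalty weight.
#' @return A non-negative scalar.
#' @export
objective_ionmf <- function(data, W, H_list, alpha) {
  X <- check_views(as_views(data))
  resid <- sum(vapply(seq_along(X), function(I) {
    frob2(X[[I]] - W %*% H_list[[I]])
  }, numeric(1)))
  pen <- sum(vapply(seq_along(X), function(I) {
    HHt <- tcrossprod(H_list[[I]])
    frob2(HHt - diag(nrow(HHt)))
  }, numeric(1)))
  resid + alpha * pen
}

## ---------------------------------------------------------------------------
## Shared-coefficient models (graph-regularized and plain)
## ---------------------------------------------------------------------------

#' Fit the graph-regularized shared-coefficient factorization
#'
#' Factors every view as `X_I ~ W U_I V` with a shared basis `W` (clustered
#' to group samples), view-specific subspace transforms `U_I`, and a shared
#' coefficient matrix `V` (whose columns rank co-differential features),
#' penalized by `lambda_I tr(W' L_I W)` so that samples adjacent in each
#' view's K-nearest-neighbor graph obtain similar basis rows.
#'
#' Factors are initialized from seeded uniform(0, 1) draws (order: `W`, then
#' each `U_I` in view order, then `V`) and refined by multiplicative updates
#' in the order `W`, all `U_I`, `V` per sweep. By default the W-update uses
#' the non-negativity-preserving Laplacian split: `lambda_I E_I W` joins the
#' numerator and `lambda_I D_I W` the denominator, which has the same
#' stationary points as keeping `lambda_I L_I W` in the denominator. With all
#' `lambda_I = 0` the iterates coincide exactly with [mvnmf_fit()].
#'
#' @param data A [multiview_dataset()] (or list of non-negative matrices of
#'   identical dimensions).
#' @param graphs List of [knn_adjacency()] graphs over the samples, one per
#'   view; may be `NULL` when all `lambdas` are zero.
#' @param config A [solver_config()]; `k`, `r`, `lambdas`, `max_iter`, `tol`,
#'   `seed`, `eps` and `laplacian_update` are honored.
#' @return A `factorization_result` with `W`, `U_list`, `V`,
#'   `objective_history` (one value per sweep), `converged`, `n_iter`.
#' @examples
#' gt <- generate_factor_model(synthetic_spec(n_samples = 30, n_features = 40,
#'                                            n_views = 2, seed = 7))
#' graphs <- lapply(gt$dataset$views, knn_adjacency, K = 5)
#' fit <- gmvnmf_fit(gt$dataset, graphs,
#'                   solver_config(k = 3, r = 2, lambdas = 1, seed = 7))
#' fit
#' @export
gmvnmf_fit <- function(data, graphs = NULL, config) {
  stopifnot(inherits(config, "solver_config"))
  X <- check_views(as_views(data))
  d <- length(X)
  n <- nrow(X[[1]]); m <- ncol(X[[1]])
  k <- config$k; r <- config$r; eps <- config$eps
  if (k > n) stop2(sprintf("k = %d exceeds the number of samples n = %d", k, n))
  if (r >= k && k > 1) stop2(sprintf("r = %d must be <= k - 1 = %d", r, k - 1))
  if (k == 1 && r != 1) stop2("with k = 1, r must be 1")
  lambdas <- rep_len(config$lambdas, d)
  use_graph <- lambdas > 0
  if (any(use_graph)) {
    if (is.null(graphs) || length(graphs) != d) {
      stop2("`graphs` must supply one affinity_graph per view when lambdas > 0")
    }
    for (I in which(use_graph)) {
      if (nrow(graphs[[I]]$L) != n) stop2("graph size does not match sample count")
    }
  }
  split <- config$laplacian_update == "split"

  set.seed(config$seed)
  W <- matrix(stats::runif(n * k), n, k)
  U <- lapply(seq_len(d), function(I) matrix(stats::runif(k * r), k, r))
  V <- matrix(stats::runif(r * m), r, m)

  history <- numeric(config$max_iter + 1L)
  history[1] <- objective_gmvnmf(X, graphs, W, U, V, lambdas)
  converged <- FALSE
  zero_warned <- FALSE
  for (it in seq_len(config$max_iter)) {
    ## W update (old U, V)
    num <- matrix(0, n, k); den <- matrix(0, n, k)
    for (I in seq_len(d)) {
      UV <- U[[I]] %*% V
      num <- num + X[[I]] %*% t(UV)
      den <- den + W %*% tcrossprod(UV)
      if (use_graph[I]) {
        if (split) {
          num <- num + lambdas[I] * (graphs[[I]]$E %*% W)
          den <- den + lambdas[I] * (graphs[[I]]$degrees * W)
        } else {
          den <- den + lambdas[I] * (graphs[[I]]$L %*% W)
        }
      }
    }
    W <- W * num / (den + eps)

    ## U updates (new W)
    WtW <- crossprod(W)
    WtX <- lapply(X, function(x) crossprod(W, x))
    VVt <- tcrossprod(V)
    for (I in seq_len(d)) {
      numU <- WtX[[I]] %*% t(V)
      denU <- WtW %*% U[[I]] %*% VVt
      U[[I]] <- U[[I]] * numU / (denU + eps)
    }

    ## V update (new W, U)
    numV <- matrix(0, r, m); denV <- matrix(0, r, m)
    for (I in seq_len(d)) {
      numV <- numV + crossprod(U[[I]], WtX[[I]])
      denV <- denV + (crossprod(U[[I]], WtW) %*% U[[I]]) %*% V
    }
    V <- V * numV / (denV + eps)

    if (!zero_warned &&
        (any(colSums(W) == 0) || any(rowSums(V) == 0))) {
      warning("a factor row/column collapsed to zero and will stay zero",
              call. = FALSE)
      zero_warned <- TRUE
    }

    history[it + 1] <- objective_gmvnmf(X, graphs, W, U, V, lambdas)
    if (rel_change(history[it], history[it + 1], eps) < config$tol) {
      converged <- TRUE
      history <- history[seq_len(it + 1)]
      break
    }
  }
  new_result("gmvnmf", history, converged, config,
             W = W, U_list = U, V = V, lambdas = lambdas)
}

#' Fit the plain shared-coefficient factorization
#'
#' The special case of [gmvnmf_fit()] without graph regularization
#' (`lambda_I = 0` for every view); no graphs are needed.
#'
#' @inheritParams gmvnmf_fit
#' @return A `factorization_result` as for [gmvnmf_fit()], with
#'   `model = "mvnmf"`.
#' @export
mvnmf_fit <- function(data, config) {
  config$lambdas <- 0
  res <- gmvnmf_fit(data, graphs = NULL, config = config)
  res$model <- "mvnmf"
  res
}

## ---------------------------------------------------------------------------
## Joint-model baselines
## ---------------------------------------------------------------------------

#' Fit the joint factorization baseline
#'
#' Factors every view as `X_I ~ W H_I` with a shared basis `W` and per-view
#' coefficients `H_I`, by the classical alternating multiplicative updates
#' (the W-update pools numerator and denominator across views). With a
#' single view this is exactly two-factor NMF. Initialization order: `W`,
#' then each `H_I` in view order.
#'
#' @inheritParams gmvnmf_fit
#' @return A `factorization_result` with `W`, `H_list`, `objective_history`,
#'   `converged`, `n_iter`.
#' @export
jnmf_fit <- function(data, config) {
  stopifnot(inherits(config, "solver_config"))
  X <- check_views(as_views(data))
  d <- length(X)
  n <- nrow(X[[1]]); m <- ncol(X[[1]])
  k <- config$k; eps <- config$eps
  if (k > n) stop2(sprintf("k = %d exceeds the number of samples n = %d", k, n))

  set.seed(config$seed)
  W <- matrix(stats::runif(n * k), n, k)
  H <- lapply(seq_len(d), function(I) matrix(stats::runif(k * m), k, m))

  history <- numeric(config$max_iter + 1L)
  history[1] <- objective_jnmf(X, W, H)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    num <- matrix(0, n, k); den <- matrix(0, n, k)
    for (I in seq_len(d)) {
      num <- num + X[[I]] %*% t(H[[I]])
      den <- den + W %*% tcrossprod(H[[I]])
    }
    W <- W * num / (den + eps)
    WtW <- crossprod(W)
    for (I in seq_len(d)) {
      H[[I]] <- H[[I]] * crossprod(W, X[[I]]) / (WtW %*% H[[I]] + eps)
    }
    history[it + 1] <- objective_jnmf(X, W, H)
    if (rel_change(history[it], history[it + 1], eps) < config$tol) {
      converged <- TRUE
      history <- history[seq_len(it + 1)]
      break
    }
  }
  new_result("jnmf", history, converged, config, W = W, H_list = H)
}

#' Fit the integrative factorization with heterogeneous terms
#'
#' Minimizes `sum_I ||X_I - (W + V_I) H_I||_F^2 + lambda sum_I ||V_I H_I||_F^2`
#' where `W` captures the homogeneous effect shared across views and `V_I`
#' view-specific heterogeneous deviations, shrunk by `lambda`. The
#' multiplicative updates follow from the same KKT construction as the
#' graph-regularized model:
#' \itemize{
#'   \item `W <- W * (sum_I X_I H_I') / (sum_I (W + V_I) H_I H_I')`
#'   \item `V_I <- V_I * (X_I H_I') / ((W + V_I) H_I H_I' + lambda V_I H_I H_I')`
#'   \item `H_I <- H_I * (B_I' X_I) / (B_I' B_I H_I + lambda V_I' V_I H_I)`,
#'     `B_I = W + V_I`.
#' }
#' With `lambda = 0` and `V_I` initialized to zero (a multiplicative fixed
#' point) the trajectory coincides with [jnmf_fit()].
#'
#' @inheritParams gmvnmf_fit
#' @param v_init `"uniform"` (default) draws the heterogeneous terms from
#'   uniform(0, 1) after `W` and the `H_I`; `"zero"` starts them at zero,
#'   where they remain.
#' @return A `factorization_result` with `W`, `H_list`, `V_list`.
#' @export
inmf_fit <- function(data, config, v_init = c("uniform", "zero")) {
  stopifnot(inherits(config, "solver_config"))
  v_init <- match.arg(v_init)
  X <- check_views(as_views(data))
  d <- length(X)
  n <- nrow(X[[1]]); m <- ncol(X[[1]])
  k <- config$k; eps <- config$eps; lam <- config$lambda_inmf
  if (k > n) stop2(sprintf("k = %d exceeds the number of samples n = %d", k, n))

  set.seed(config$seed)
  W <- matrix(stats::runif(n * k), n, k)
  H <- lapply(seq_len(d), function(I) matrix(stats::runif(k * m), k, m))
  Vl <- if (v_init == "uniform") {
    lapply(seq_len(d), function(I) matrix(stats::runif(n * k), n, k))
  } else {
    lapply(seq_len(d), function(I) matrix(0, n, k))
  }

  history <- numeric(config$max_iter + 1L)
  history[1] <- objective_inmf(X, W, H, Vl, lam)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    HHt <- lapply(H, tcrossprod)
    num <- matrix(0, n, k); den <- matrix(0, n, k)
    for (I in seq_len(d)) {
      num <- num + X[[I]] %*% t(H[[I]])
      den <- den + (W + Vl[[I]]) %*% HHt[[I]]
    }
    W <- W * num / (den + eps)
    for (I in seq_len(d)) {
      numV <- X[[I]] %*% t(H[[I]])
      denV <- (W + Vl[[I]]) %*% HHt[[I]] + lam * (Vl[[I]] %*% HHt[[I]])
      Vl[[I]] <- Vl[[I]] * numV / (denV + eps)
    }
    for (I in seq_len(d)) {
      B <- W + Vl[[I]]
      numH <- crossprod(B, X[[I]])
      denH <- crossprod(B) %*% H[[I]] + lam * (crossprod(Vl[[I]]) %*% H[[I]])
      H[[I]] <- H[[I]] * numH / (denH + eps)
    }
    history[it + 1] <- objective_inmf(X, W, H, Vl, lam)
    if (rel_change(history[it], history[it + 1], eps) < config$tol) {
      converged <- TRUE
      history <- history[seq_len(it + 1)]
      break
    }
  }
  new_result("inmf", history, converged, config,
             W = W, H_list = H, V_list = Vl)
}

#' Fit the orthogonality-regularized joint factorization
#'
#' Minimizes `sum_I ||X_I - W H_I||_F^2 + alpha ||H_I H_I' - Id||_F^2`, which
#' drives the per-view coefficient rows towards orthonormality and hence
#' sparse, non-overlapping solutions. Multiplicative updates (KKT-derived):
#' \itemize{
#'   \item `W` as in [jnmf_fit()];
#'   \item `H_I <- H_I * (W' X_I + 2 alpha H_I) /
#'     (W' W H_I + 2 alpha H_I H_I' H_I)`.
#' }
#' With `alpha = 0` the iterates coincide exactly with [jnmf_fit()].
#'
#' @inheritParams gmvnmf_fit
#' @return A `factorization_result` with `W`, `H_list`.
#' @export
ionmf_fit <- function(data, config) {
  stopifnot(inherits(config, "solver_config"))
  X <- check_views(as_views(data))
  d <- length(X)
  n <- nrow(X[[1]]); m <- ncol(X[[1]])
  k <- config$k; eps <- config$eps; alpha <- config$alpha
  if (k > n) stop2(sprintf("k = %d exceeds the number of samples n = %d", k, n))

  set.seed(config$seed)
  W <- matrix(stats::runif(n * k), n, k)
  H <- lapply(seq_len(d), function(I) matrix(stats::runif(k * m), k, m))

  history <- numeric(config$max_iter + 1L)
  history[1] <- objective_ionmf(X, W, H, alpha)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    num <- matrix(0, n, k); den <- matrix(0, n, k)
    for (I in seq_len(d)) {
      num <- num + X[[I]] %*% t(H[[I]])
      den <- den + W %*% tcrossprod(H[[I]])
    }
    W <- W * num / (den + eps)
    WtW <- crossprod(W)
    for (I in seq_len(d)) {
      numH <- crossprod(W, X[[I]])
      denH <- WtW %*% H[[I]]
      if (alpha > 0) {
        numH <- numH + 2 * alpha * H[[I]]
        denH <- denH + 2 * alpha * (tcrossprod(H[[I]]) %*% H[[I]])
      }
      H[[I]] <- H[[I]] * numH / (denH + eps)
    }
    history[it + 1] <- objective_ionmf(X, W, H, alpha)
    if (rel_change(history[it], history[it + 1], eps) < config$tol) {
      converged <- TRUE
      history <- history[seq_len(it + 1)]
      break
    }
  }
  new_result("ionmf", history, converged, config, W = W, H_list = H)
}

#' Fit any of the five models by name
#'
#' Thin dispatcher used by the command-line interface and grid search.
#'
#' @inheritParams gmvnmf_fit
#' @param model One of `"gmvnmf"`, `"mvnmf"`, `"jnmf"`, `"inmf"`, `"ionmf"`.
#' @return A `factorization_result`.
#' @export
fit_model <- function(model, data, config, graphs = NULL) {
  switch(match.arg(model, c("gmvnmf", "mvnmf", "jnmf", "inmf", "ionmf")),
         gmvnmf = gmvnmf_fit(data, graphs, config),
         mvnmf = mvnmf_fit(data, config),
         jnmf = jnmf_fit(data, config),
         inmf = inmf_fit(data, config),
         ionmf = ionmf_fit(data, config))
}

#' Write a factorization result to a directory
#'
#' Factors go to full-precision CSV files, the objective trajectory to
#' `objective_history.csv`, and model/config/convergence metadata to
#' `manifest.json`, so a written result can be re-read bit-exactly.
#'
#' @param result A `factorization_result`.
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_result <- function(result, dir) {
  stopifnot(inherits(result, "factorization_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  write_matrix_csv(result$W, file.path(dir, "W.csv"))
  files$W <- "W.csv"
  for (nm in intersect(c("U_list", "H_list", "V_list"), names(result))) {
    for (I in seq_along(result[[nm]])) {
      f <- sprintf("%s_%d.csv", sub("_list$", "", nm), I)
      write_matrix_csv(result[[nm]][[I]], file.path(dir, f))
      files[[nm]][I] <- f
    }
  }
  if (!is.null(result$V)) {
    write_matrix_csv(result$V, file.path(dir, "V.csv"))
    files$V <- "V.csv"
  }
  utils::write.csv(
    data.frame(iteration = seq_along(result$objective_history),
               objective = sprintf("%.17g", result$objective_history)),
    file.path(dir, "objective_history.csv"), row.names = FALSE, quote = FALSE)
  manifest <- list(kind = "factorization_result", model = result$model,
                   files = files, n_iter = result$n_iter,
                   converged = result$converged,
                   config = unclass(result$config))
  path <- file.path(dir, "manifest.json")
  write_json_file(manifest, path)
  invisible(path)
}

#' Read a factorization result written by [write_result()]
#' @param dir Directory containing `manifest.json`.
#' @return A `factorization_result`.
#' @export
read_result <- function(dir) {
  manifest <- read_json_file(file.path(dir, "manifest.json"))
  res <- list(model = manifest$model,
              W = read_matrix_csv(file.path(dir, manifest$files$W)))
  for (nm in intersect(c("U_list", "H_list", "V_list"), names(manifest$files))) {
    res[[nm]] <- lapply(manifest$files[[nm]],
                        function(f) read_matrix_csv(file.path(dir, f)))
  }
  if (!is.null(manifest$files$V)) {
    res$V <- read_matrix_csv(file.path(dir, manifest$files$V))
  }
  hist <- utils::read.csv(file.path(dir, "objective_history.csv"))
  res$objective_history <- as.numeric(hist$objective)
  res$converged <- manifest$converged
  res$n_iter <- manifest$n_iter
  cfg <- manifest$config
  res$config <- do.call(solver_config, cfg[setdiff(names(cfg), character(0))])
  structure(res, class = "factorization_result")
}
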