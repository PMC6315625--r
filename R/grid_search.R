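## Exhaustive hyper-parameter search over (k, r, lambda), scoring each fitted
## model with a user-supplied function (typically clustering accuracy against
## known labels).

#' Grid search over ranks and regularization strength
#'
#' Evaluates every admissible combination of `k`, `r` and `lambda` for a
#' model and returns the best-scoring configuration together with the full
#' score table. `r` values violating `r <= k - 1` are skipped rather than
#' evaluated, and all views share one `lambda`, following the convention of
#' tying the per-view weights.
#'
#' @param data A [multiview_dataset()].
#' @param graphs Per-view [knn_adjacency()] graphs (needed when any
#'   `lambda > 0` and `model = "gmvnmf"`).
#' @param k_values Integer vector of basis widths to try.
#' @param r_values Integer vector of coefficient ranks to try, or `NULL` to
#'   use `k - 1` for every `k`.
#' @param lambda_values Numeric vector of shared regularization weights
#'   (ignored for models without a graph term).
#' @param score_fn Function mapping a `factorization_result` to a single
#'   numeric score (higher is better), e.g.
#'   `function(fit) clustering_accuracy(truth, cluster_basis(fit$W, 2))`.
#' @param model Model name passed to [fit_model()].
#' @param base_config A [solver_config()] supplying `max_iter`, `tol`,
#'   `seed`, `eps` for every grid point.
#' @return A list with `best_config` (a [solver_config()]), `best_score`, and
#'   `table` (a data.frame with columns `k`, `r`, `lambda`, `score`,
#'   `converged`, `n_iter`).
#' @export
grid_search <- function(data, graphs = NULL, k_values, r_values = NULL,
                        lambda_values = 0, score_fn,
                        model = "gmvnmf",
                        base_config = solver_config(k = max(k_values))) {
  stopifnot(is.function(score_fn))
  uses_r <- model %in% c("gmvnmf", "mvnmf")
  uses_lambda <- model == "gmvnmf"
  if (!uses_lambda) lambda_values <- 0
  rows <- list()
  for (k in k_values) {
    rs <- if (!uses_r) NA_integer_
          else if (is.null(r_values)) max(1L, k - 1L)
          else r_values[r_values <= k - 1 | (k == 1 & r_values == 1)]
    for (r in rs) {
      for (lam in lambda_values) {
        rows[[length(rows) + 1L]] <- list(k = k, r = r, lambda = lam)
      }
    }
  }
  if (!length(rows)) stop2("parameter grid is empty (check r <= k - 1)")
  tab <- data.frame(k = integer(0), r = integer(0), lambda = numeric(0),
                    score = numeric(0), converged = logical(0),
                    n_iter = integer(0))
  best <- NULL
  for (row in rows) {
    cfg <- base_config
    cfg$k <- as.integer(row$k)
    cfg$r <- if (is.na(row$r)) max(1L, cfg$k - 1L) else as.integer(row$r)
    cfg$lambdas <- row$lambda
    fit <- fit_model(model, data, cfg, graphs)
    sc <- score_fn(fit)
    tab <- rbind(tab, data.frame(k = row$k, r = row$r, lambda = row$lambda,
                                 score = sc, converged = fit$converged,
                                 n_iter = fit$n_iter))
    if (is.null(best) || sc > best$score) {
      best <- list(config = cfg, score = sc)
    }
  }
  list(best_config = best$config, best_score = best$score, table = tab)
}
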