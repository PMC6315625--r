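## Sample clustering on the shared basis and its evaluation against ground
## truth: accuracy under the best label permutation and the pairwise
## co-membership metrics (recall, precision, F-measure).

#' Cluster samples from the shared basis matrix
#'
#' Runs K-means on the rows of `W` with `n_restarts` seeded initializations
#' and keeps the partition with the smallest within-cluster sum of squares.
#' Deterministic given `seed`.
#'
#' @param W Numeric matrix, one sample per row (typically the shared basis of
#'   a `factorization_result`).
#' @param n_clusters Number of clusters, at most `nrow(W)`.
#' @param seed Integer seed; restart `s` uses `seed + s - 1`.
#' @param n_restarts Number of K-means restarts (default 20).
#' @return Integer cluster labels of length `nrow(W)`.
#' @export
cluster_basis <- function(W, n_clusters, seed = 1L, n_restarts = 20L) {
  W <- assert_matrix(W, "W")
  n <- nrow(W)
  n_clusters <- assert_count(n_clusters, "n_clusters")
  if (n_clusters > n) {
    stop2(sprintf("n_clusters = %d exceeds the number of samples %d",
                  n_clusters, n))
  }
  n_distinct <- nrow(unique(W))
  if (n_distinct <= n_clusters) {
    # as many clusters as distinct rows: each distinct row is its own cluster
    return(as.integer(factor(apply(W, 1, paste, collapse = "\r"))))
  }
  best <- NULL
  for (s in seq_len(n_restarts)) {
    set.seed(seed + s - 1L)
    km <- suppressWarnings(
      stats::kmeans(W, centers = n_clusters, nstart = 1, iter.max = 100))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  as.integer(best$cluster)
}

## Exact minimum-cost assignment (Hungarian algorithm, O(n^3) potentials
## formulation) on a square cost matrix. Hand-rolled because no installed
## package exposes an exact linear sum assignment solver; validated against
## brute-force permutation enumeration in the tests.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match_of_row <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) match_of_row[p[j + 1]] <- j
  match_of_row
}

canon_labels <- function(x) as.integer(factor(x))

#' Clustering accuracy under optimal label matching
#'
#' The fraction of samples whose predicted cluster, after the permutation of
#' cluster identities that maximizes agreement (found exactly by minimum-cost
#' assignment on the negated confusion matrix), matches the true label.
#' Invariant to relabeling of either input.
#'
#' @param true_labels,predicted_labels Equal-length label vectors (any
#'   atomic type; treated as categorical).
#' @return Accuracy in \[0, 1\].
#' @examples
#' clustering_accuracy(c(1, 1, 2), c(2, 2, 1))  # 1: labels are permuted
#' @export
clustering_accuracy <- function(true_labels, predicted_labels) {
  map <- best_label_map(true_labels, predicted_labels)
  map$n_matched / length(true_labels)
}

best_label_map <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop2("label vectors must have equal length")
  }
  s <- canon_labels(true_labels)
  r <- canon_labels(predicted_labels)
  conf <- as.matrix(table(r, s))  # predicted x true counts
  q <- max(dim(conf))
  cost <- matrix(0, q, q)
  cost[seq_len(nrow(conf)), seq_len(ncol(conf))] <- -conf
  assign <- solve_assignment(cost)
  matched <- sum(conf[cbind(seq_len(nrow(conf)),
                            pmin(assign[seq_len(nrow(conf))], ncol(conf)))] *
                   (assign[seq_len(nrow(conf))] <= ncol(conf)))
  list(mapping = assign, n_matched = matched, confusion = conf)
}

#' Pairwise clustering recall, precision and F-measure
#'
#' Over all unordered sample pairs: a true positive is a pair sharing both
#' its true and its predicted cluster; a false negative shares the true but
#' not the predicted cluster; a false positive shares the predicted but not
#' the true cluster. `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `F = 2 / (1/recall + 1/precision)`; any 0/0 is defined as 0. Invariant to
#' relabeling of either input.
#'
#' @inheritParams clustering_accuracy
#' @return Named numeric vector `c(recall, precision, f_measure)`.
#' @export
pairwise_metrics <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop2("label vectors must have equal length")
  }
  if (length(true_labels) < 2) stop2("need at least 2 samples")
  tab <- table(true_labels, predicted_labels)
  tp <- sum(choose(tab, 2))
  tp_fn <- sum(choose(rowSums(tab), 2))
  tp_fp <- sum(choose(colSums(tab), 2))
  recall <- if (tp_fn > 0) tp / tp_fn else 0
  precision <- if (tp_fp > 0) tp / tp_fp else 0
  f <- if (recall > 0 && precision > 0) 2 / (1 / recall + 1 / precision) else 0
  c(recall = recall, precision = precision, f_measure = f)
}

#' Full clustering evaluation report
#'
#' Combines [clustering_accuracy()] and [pairwise_metrics()] with the label
#' mapping used for accuracy.
#'
#' @inheritParams clustering_accuracy
#' @return An object of class `clustering_report` with `predicted_labels`,
#'   `true_labels`, `ac`, `recall`, `precision`, `f_measure`, `mapping`.
#' @export
clustering_report <- function(true_labels, predicted_labels) {
  map <- best_label_map(true_labels, predicted_labels)
  pm <- pairwise_metrics(true_labels, predicted_labels)
  structure(list(predicted_labels = predicted_labels,
                 true_labels = true_labels,
                 ac = map$n_matched / length(true_labels),
                 recall = unname(pm["recall"]),
                 precision = unname(pm["precision"]),
                 f_measure = unname(pm["f_measure"]),
                 mapping = map$mapping),
            class = "clustering_report")
}

#' @export
print.clustering_report <- function(x, ...) {
  cat(sprintf(paste0("<clustering_report> n = %d\n",
                     "  AC        %.4f\n  recall    %.4f\n",
                     "  precision %.4f\n  F-measure %.4f\n"),
              length(x$true_labels), x$ac, x$recall, x$precision, x$f_measure))
  invisible(x)
}

#' Repeated factorize-and-cluster evaluation
#'
#' Re-runs factorization and K-means `repeats` times with fresh seeds
#' (re-randomizing both the factor initialization and the K-means restarts)
#' and reports the mean and variance of each metric, mirroring how stochastic
#' clustering pipelines are usually summarized.
#'
#' @inheritParams gmvnmf_fit
#' @param model Model name for [fit_model()].
#' @param true_labels Ground-truth labels (their distinct count sets the
#'   number of clusters).
#' @param repeats Number of independent repetitions.
#' @param n_restarts K-means restarts per repetition.
#' @return A data.frame with one row per repeat and columns `repeat_id`,
#'   `ac`, `recall`, `precision`, `f_measure`; means/variances are attached
#'   as attributes `mean` and `var`.
#' @export
evaluate_clustering <- function(model, data, config, true_labels,
                                graphs = NULL, repeats = 1L,
                                n_restarts = 20L) {
  n_clusters <- length(unique(true_labels))
  rows <- lapply(seq_len(repeats), function(rep) {
    cfg <- config
    cfg$seed <- config$seed + rep - 1L
    fit <- fit_model(model, data, cfg, graphs)
    pred <- cluster_basis(fit$W, n_clusters, seed = cfg$seed,
                          n_restarts = n_restarts)
    rep_report <- clustering_report(true_labels, pred)
    data.frame(repeat_id = rep, ac = rep_report$ac,
               recall = rep_report$recall,
               precision = rep_report$precision,
               f_measure = rep_report$f_measure)
  })
  out <- do.call(rbind, rows)
  metrics <- c("ac", "recall", "precision", "f_measure")
  attr(out, "mean") <- vapply(out[metrics], mean, numeric(1))
  attr(out, "var") <- vapply(out[metrics], stats::var, numeric(1))
  out
}
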