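## Synthetic multi-view data with known ground truth: planted sample
## clusters shared across views, a planted set of co-differential features
## visible in every view, per-view noise, and an optional within-cluster
## manifold (smooth curve) structure that makes graph regularization
## informative.

#' Specification of a synthetic multi-view dataset
#'
#' Defaults describe a small three-view cohort (150 samples, 300 features,
#' 3 balanced clusters, 50 planted co-differential features) that every
#' solver handles in seconds.
#'
#' @param n_samples,n_features,n_views Dataset dimensions.
#' @param n_clusters Number of planted sample clusters (>= 2).
#' @param cluster_proportions Cluster size proportions (summing to 1);
#'   defaults to balanced clusters.
#' @param n_diff_genes Number of planted co-differential features.
#' @param signal Mean loading of a differential feature in its active
#'   component (and of a sample on its cluster's basis component).
#' @param background Mean loading elsewhere; must be smaller than `signal`.
#' @param noise_sd Per-view noise standard deviations (half-normal noise is
#'   added before row normalization); a scalar is recycled.
#' @param manifold If `TRUE`, within-cluster samples are placed along a
#'   smooth arc in latent space instead of a point mass, so that K-nearest
#'   neighbors carry information the factorization alone does not.
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 150L, n_features = 300L, n_views = 3L,
                           n_clusters = 3L, cluster_proportions = NULL,
                           n_diff_genes = 50L, signal = 1, background = 0.1,
                           noise_sd = 0.05, manifold = FALSE, seed = 1L) {
  n_samples <- assert_count(n_samples, "n_samples")
  n_features <- assert_count(n_features, "n_features")
  n_views <- assert_count(n_views, "n_views")
  n_clusters <- assert_count(n_clusters, "n_clusters")
  if (n_clusters < 2) stop2("`n_clusters` must be >= 2")
  if (n_clusters > n_samples) stop2("more clusters than samples")
  n_diff_genes <- assert_count(n_diff_genes, "n_diff_genes")
  if (n_diff_genes > n_features) stop2("`n_diff_genes` exceeds `n_features`")
  if (is.null(cluster_proportions)) {
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  }
  if (length(cluster_proportions) != n_clusters ||
      abs(sum(cluster_proportions) - 1) > 1e-8 ||
      any(cluster_proportions <= 0)) {
    stop2("`cluster_proportions` must be positive and sum to 1")
  }
  if (signal <= 0 || background < 0 || background >= signal) {
    stop2("need 0 <= background < signal")
  }
  noise_sd <- rep_len(noise_sd, n_views)
  if (any(noise_sd < 0)) stop2("`noise_sd` must be non-negative")
  structure(list(n_samples = n_samples, n_features = n_features,
                 n_views = n_views, n_clusters = n_clusters,
                 cluster_proportions = cluster_proportions,
                 n_diff_genes = n_diff_genes, signal = signal,
                 background = background, noise_sd = noise_sd,
                 manifold = isTRUE(manifold), seed = as.integer(seed)),
            class = "synthetic_spec")
}

cluster_counts <- function(spec) {
  bounds <- round(cumsum(spec$cluster_proportions) * spec$n_samples)
  counts <- diff(c(0, bounds))
  if (any(counts < 1)) stop2("a cluster received no samples; increase n_samples")
  counts
}

generate_multiview <- function(spec, manifold) {
  n <- spec$n_samples; m <- spec$n_features; d <- spec$n_views
  C <- spec$n_clusters
  k <- C
  r <- max(1L, C - 1L)
  counts <- cluster_counts(spec)
  labels <- rep(seq_len(C), counts)
  sample_ids <- sprintf("s%03d", seq_len(n))
  feature_ids <- sprintf("g%04d", seq_len(m))

  set.seed(spec$seed)
  diff_idx <- sort(sample.int(m, spec$n_diff_genes))
  view_scale <- stats::runif(d, 0.8, 1.2)

  ## shared basis: block structure, optionally bent into an arc per cluster
  W <- matrix(spec$background * stats::runif(n * k), n, k)
  if (!manifold) {
    for (i in seq_len(n)) {
      W[i, labels[i]] <- spec$signal * stats::runif(1, 0.8, 1.2)
    }
  } else {
    for (c in seq_len(C)) {
      idx <- which(labels == c)
      nc <- length(idx)
      t_pos <- if (nc > 1) (seq_len(nc) - 1) / (nc - 1) else 0
      t_pos <- pmin(pmax(t_pos + stats::rnorm(nc, 0, 0.02), 0), 1)
      theta <- (pi / 2) * t_pos
      nxt <- c %% k + 1L
      W[idx, c] <- spec$signal * (0.7 + 0.3 * cos(theta))
      W[idx, nxt] <- W[idx, nxt] + spec$signal * 0.3 * sin(theta)
    }
  }

  ## Each view's subspace transform sends distinct clusters to distinct
  ## non-negative latent directions (angles spread over the first quadrant of
  ## the leading two coordinates), so every view carries the shared cluster
  ## structure -- the premise of a shared-basis model. With r = 1 the latent
  ## space is a half-line and clusters differ only in magnitude, which
  ## per-row min-max scaling largely removes; r >= 2 is the informative case.
  U <- lapply(seq_len(d), function(I) {
    Umat <- matrix(0.2 * stats::runif(k * r), k, r)
    for (c in seq_len(k)) {
      mag <- view_scale[I] * stats::runif(1, 0.9, 1.1)
      if (r >= 2) {
        phi <- (c - 1) / (k - 1) * (pi / 2) + stats::rnorm(1, 0, 0.05)
        phi <- min(max(phi, 0), pi / 2)
        Umat[c, 1] <- Umat[c, 1] + mag * cos(phi)
        Umat[c, 2] <- Umat[c, 2] + mag * sin(phi)
      } else {
        Umat[c, 1] <- Umat[c, 1] + mag * c / k
      }
    }
    Umat
  })

  V <- matrix(spec$background * stats::runif(r * m), r, m)
  V[, diff_idx] <- spec$signal * stats::runif(r * spec$n_diff_genes, 0.8, 1.2)

  views <- lapply(seq_len(d), function(I) {
    X <- W %*% U[[I]] %*% V
    if (spec$noise_sd[I] > 0) {
      X <- X + abs(matrix(stats::rnorm(n * m, 0, spec$noise_sd[I]), n, m))
    }
    dimnames(X) <- list(sample_ids, feature_ids)
    minmax_rows(X)
  })
  dataset <- multiview_dataset(views, sample_ids, feature_ids,
                               view_names = paste0("view", seq_len(d)))
  truth <- structure(list(labels = labels,
                          diff_gene_ids = feature_ids[diff_idx],
                          W = W, U_list = U, V = V, spec = spec),
                     class = "ground_truth")
  list(dataset = dataset, truth = truth)
}

#' Generate multi-view data from planted factors
#'
#' Builds `X_I = W* U_I* V* + |noise|` from a block-structured basis `W*`
#' (cluster c's samples load on component c), view-specific random subspace
#' transforms `U_I*`, and a shared coefficient matrix `V*` whose planted
#' differential columns load near `signal` while all other columns stay near
#' `background`. Each view then gets half-normal noise and per-row min-max
#' scaling, so the result satisfies the [multiview_dataset()] invariants.
#' Reproducible given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `dataset` (a [multiview_dataset()]) and `truth`
#'   (labels, planted differential feature ids, and the planted factors).
#' @export
generate_factor_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  generate_multiview(spec, manifold = FALSE)
}

#' Generate the manifold variant of the synthetic data
#'
#' As [generate_factor_model()], but each cluster's samples are spread along
#' a smooth arc between its own basis component and the next one, so samples
#' near a cluster's far end lean towards the neighboring component. K-nearest
#' neighbors along the arc then carry cluster information that the
#' factorization residual alone blurs — the regime graph regularization is
#' designed for. Labels and planted feature ids are identical to the
#' factor-model path under the same seed; with `spec$manifold = FALSE` the
#' output *is* the factor-model output.
#'
#' @inheritParams generate_factor_model
#' @return As [generate_factor_model()].
#' @export
generate_manifold_variant <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  generate_multiview(spec, manifold = spec$manifold)
}

#' Write a synthetic dataset, its labels and ground truth to a directory
#'
#' Produces the same layout as [write_dataset()] plus `labels.tsv`
#' (sample_id, label), `diff_genes.txt` (one planted feature id per line) and
#' `spec.json`.
#'
#' @param generated Output of [generate_factor_model()] or
#'   [generate_manifold_variant()].
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_synthetic <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- generated$truth
  utils::write.table(
    data.frame(sample_id = generated$dataset$sample_ids,
               label = truth$labels),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(truth$diff_gene_ids, file.path(dir, "diff_genes.txt"))
  write_json_file(unclass(truth$spec), file.path(dir, "spec.json"))
  write_dataset(generated$dataset, dir,
                extra = list(labels_file = "labels.tsv",
                             diff_genes_file = "diff_genes.txt",
                             spec_file = "spec.json"))
}

#' Read a two-column labels TSV (sample_id, label)
#' @param path Path to the TSV.
#' @return Integer label vector named by sample id.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stats::setNames(as.integer(factor(df[[2]])), df[[1]])
}
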