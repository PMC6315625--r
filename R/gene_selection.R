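## Feature (gene) ranking from the shared coefficient matrix V: a gene's
## score aggregates its column of V across the latent components, so genes
## loaded jointly across all views rank highest.

#' Score features from the shared coefficient matrix
#'
#' Each column of `V` (one per feature) is collapsed to a single non-negative
#' score. The default is the Euclidean norm of the column; `l1_norm` and
#' `max` are alternatives. All three are positively homogeneous, so rescaling
#' `V` never changes the ranking; a zero column always scores 0.
#'
#' @param V Non-negative `r x m` coefficient matrix (features in columns).
#' @param method `"l2_norm"` (default), `"l1_norm"` or `"max"`.
#' @return Numeric vector of `m` scores, named by `colnames(V)` when present.
#' @export
gene_scores <- function(V, method = "l2_norm") {
  V <- assert_nonneg(V, "V")
  methods <- c("l2_norm", "l1_norm", "max")
  if (!is.character(method) || length(method) != 1 || !(method %in% methods)) {
    stop2(sprintf("unknown score method %s; options: %s",
                  deparse(method), paste(methods, collapse = ", ")))
  }
  scores <- switch(method,
                   l2_norm = sqrt(colSums(V^2)),
                   l1_norm = colSums(V),
                   max = apply(V, 2, max))
  names(scores) <- colnames(V)
  scores
}

#' Rank features and select the top N
#'
#' Sorts scores in descending order, breaking ties by feature identifier
#' (lexicographic), and records the top `min(N, m)` features.
#'
#' @param scores Numeric score vector (e.g. from [gene_scores()]).
#' @param N Number of features to select.
#' @param feature_ids Identifiers aligned with `scores`; defaults to
#'   `names(scores)`.
#' @return An object of class `gene_ranking` with `scores`, `order`
#'   (permutation sorting scores descending), `ranked_ids`, `top_n`, `method`
#'   attribute left to the caller.
#' @export
select_top <- function(scores, N, feature_ids = names(scores)) {
  N <- assert_count(N, "N")
  if (is.null(feature_ids)) feature_ids <- paste0("feature", seq_along(scores))
  if (length(feature_ids) != length(scores)) {
    stop2("feature_ids length must match scores")
  }
  ord <- order(-scores, feature_ids)
  structure(list(scores = scores, order = ord,
                 feature_ids = as.character(feature_ids),
                 ranked_ids = as.character(feature_ids[ord]),
                 top_n = as.character(feature_ids[ord][seq_len(min(N, length(scores)))]),
                 N = N),
            class = "gene_ranking")
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat(sprintf("<gene_ranking> %d features, top %d selected\n",
              length(x$scores), length(x$top_n)))
  show <- utils::head(x$order, 5)
  cat("  head:", paste(sprintf("%s (%.4g)", x$feature_ids[show],
                               x$scores[show]), collapse = ", "), "\n")
  invisible(x)
}

#' Precision and recall of a ranking against planted features
#'
#' Test-harness metric for synthetic data with known differential features:
#' the fraction of selected features that are planted (precision) and the
#' fraction of planted features selected (recall).
#'
#' @param ranking A [select_top()] result.
#' @param planted_ids Identifiers of the planted differential features; must
#'   all exist in the ranking.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
recovery_metrics <- function(ranking, planted_ids) {
  stopifnot(inherits(ranking, "gene_ranking"))
  if (!length(planted_ids)) stop2("`planted_ids` must be non-empty")
  unknown <- setdiff(planted_ids, ranking$feature_ids)
  if (length(unknown)) {
    stop2(sprintf("unknown planted ids: %s",
                  paste(utils::head(unknown, 5), collapse = ", ")))
  }
  hits <- length(intersect(ranking$top_n, planted_ids))
  c(precision = hits / length(ranking$top_n),
    recall = hits / length(planted_ids))
}

#' Write a gene ranking as TSV (rank, feature_id, score) plus a plain-text
#' top-N list (one identifier per line), suitable for manual database
#' queries.
#'
#' @param ranking A [select_top()] result.
#' @param path Output TSV path; the top-N list goes to `<path>.topN.txt`.
#' @return The TSV path, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "gene_ranking"))
  df <- data.frame(rank = seq_along(ranking$order),
                   feature_id = ranking$ranked_ids,
                   score = ranking$scores[ranking$order])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(ranking$top_n, paste0(path, ".topN.txt"))
  invisible(path)
}
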