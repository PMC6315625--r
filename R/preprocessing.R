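## Preprocessing: raw per-view matrices -> non-negative, [0,1]-scaled inputs
## shared across views, ready for the factorization models.

#' Construct a raw data view
#'
#' A raw view is one data modality (e.g. gene expression, copy-number
#' variation or methylation) as a samples-by-features numeric matrix with
#' unique sample and feature identifiers. Raw views may contain negative
#' values; they only become factorization inputs after [minmax_rows()] (see
#' [align_views()]).
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#'   Missing values are rejected unless `impute = "mean"`, which replaces each
#'   `NA` with its feature (column) mean.
#' @param sample_ids Character vector of unique row identifiers. Defaults to
#'   the matrix rownames.
#' @param feature_ids Character vector of unique column identifiers. Defaults
#'   to the matrix colnames.
#' @param impute Either `"reject"` (default; error on any `NA`) or `"mean"`.
#' @return An object of class `raw_view` with elements `values`, `sample_ids`,
#'   `feature_ids`.
#' @examples
#' v <- raw_view(matrix(1:6, 2, 3), c("s1", "s2"), c("g1", "g2", "g3"))
#' minmax_rows(v)$values
#' @export
raw_view <- function(values, sample_ids = rownames(values),
                     feature_ids = colnames(values),
                     impute = c("reject", "mean")) {
  impute <- match.arg(impute)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop2("`values` must be a numeric matrix")
  }
  if (anyNA(values)) {
    if (impute == "reject") {
      stop2("view contains missing values; set impute = \"mean\" to mean-fill")
    }
    for (j in seq_len(ncol(values))) {
      nas <- is.na(values[, j])
      if (any(nas)) values[nas, j] <- mean(values[, j], na.rm = TRUE)
    }
    if (anyNA(values)) stop2("imputation failed: a feature is entirely missing")
  }
  if (any(!is.finite(values))) stop2("view contains non-finite values")
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("feature", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values)) stop2("sample_ids length != nrow(values)")
  if (length(feature_ids) != ncol(values)) stop2("feature_ids length != ncol(values)")
  if (anyDuplicated(sample_ids)) stop2("sample_ids must be unique")
  if (anyDuplicated(feature_ids)) stop2("feature_ids must be unique")
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids),
            class = "raw_view")
}

#' @export
print.raw_view <- function(x, ...) {
  cat(sprintf("<raw_view> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a delimited view file
#'
#' Expects a header row of feature identifiers and a first column of sample
#' identifiers (samples-in-rows). Set `orientation = "features"` when the
#' file stores features in rows; the matrix is transposed after reading.
#'
#' @param path Path to a CSV or TSV file. The delimiter is inferred from the
#'   extension (`.tsv`/`.txt` -> tab, otherwise comma) unless `sep` is given.
#' @param sep Optional field separator overriding the inference.
#' @param orientation `"samples"` (default) or `"features"` in rows.
#' @inheritParams raw_view
#' @return A [raw_view()].
#' @export
read_view <- function(path, sep = NULL,
                      orientation = c("samples", "features"),
                      impute = c("reject", "mean")) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop2(sprintf("non-numeric entries in %s", path))
  if (orientation == "features") m <- t(m)
  raw_view(m, impute = impute)
}

#' Project a view onto its top principal components
#'
#' Mean-centers the features and projects samples onto the leading principal
#' axes. The sign of each component is fixed so that its largest-magnitude
#' loading is positive, making the output reproducible across platforms.
#' Feature identifiers are replaced by synthetic component names (`PC1`, ...).
#'
#' @param view A [raw_view()].
#' @param n_components Number of components to keep; must not exceed the
#'   number of available components `min(n - 1, p)`. When `NULL`, the smallest
#'   number of components explaining at least `var_explained` of the total
#'   variance is kept.
#' @param var_explained Fraction of variance to retain when `n_components` is
#'   `NULL` (default 0.95).
#' @return A [raw_view()] with `n` rows and `n_components` columns of scores.
#'   Scores can be negative; apply [minmax_rows()] before factorization.
#' @export
pca_reduce <- function(view, n_components = NULL, var_explained = 0.95) {
  stopifnot(inherits(view, "raw_view"))
  x <- view$values
  n <- nrow(x)
  if (n < 2) stop2("PCA needs at least 2 samples")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  avail <- ncol(pc$rotation)
  if (is.null(n_components)) {
    vars <- pc$sdev[seq_len(avail)]^2
    tot <- sum(vars)
    n_components <- if (tot <= 0) 1L else which(cumsum(vars) / tot >= var_explained)[1]
  }
  n_components <- assert_count(n_components, "n_components")
  if (n_components > avail) {
    stop2(sprintf("n_components = %d exceeds the %d available components (min(n - 1, p))",
                  n_components, avail))
  }
  idx <- seq_len(n_components)
  rot <- pc$rotation[, idx, drop = FALSE]
  scores <- pc$x[, idx, drop = FALSE]
  # sign convention: largest-magnitude loading of each axis is positive
  for (j in idx) {
    peak <- which.max(abs(rot[, j]))
    if (rot[peak, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", idx)
  raw_view(scores, view$sample_ids, colnames(scores))
}

#' Scale each row of a view to the unit interval
#'
#' Applies `x -> (x - min) / (max - min)` within each row. Constant rows map
#' to all zeros, which keeps the output non-negative and avoids division by
#' zero. The map is idempotent on its own output.
#'
#' @param view A [raw_view()] or a plain numeric matrix.
#' @return Same type as the input, with all entries in \[0, 1\].
#' @export
minmax_rows <- function(view) {
  is_view <- inherits(view, "raw_view")
  x <- if (is_view) view$values else assert_matrix(view, "view")
  lo <- apply(x, 1, min)
  hi <- apply(x, 1, max)
  span <- hi - lo
  out <- (x - lo) / ifelse(span > 0, span, 1)
  out[span == 0, ] <- 0
  dimnames(out) <- dimnames(x)
  if (is_view) raw_view(out, view$sample_ids, view$feature_ids) else out
}

#' Align raw views into a multi-view dataset
#'
#' Restricts every view to the samples and features present in all views, in
#' a canonical (lexicographically sorted) order, then row-scales each view to
#' \[0, 1\] with [minmax_rows()]. The result is independent of the order in
#' which views are supplied (up to the `views` list ordering itself).
#'
#' @param raw_views List of [raw_view()] objects.
#' @param view_names Optional character names for the views; defaults to the
#'   list names or `view1`, `view2`, ...
#' @param normalize Apply [minmax_rows()] per view (default `TRUE`). Disable
#'   only if the inputs are already in \[0, 1\].
#' @return A [multiview_dataset()].
#' @export
align_views <- function(raw_views, view_names = NULL, normalize = TRUE) {
  if (!length(raw_views)) stop2("need at least one view")
  if (!all(vapply(raw_views, inherits, logical(1), "raw_view"))) {
    stop2("all elements of `raw_views` must be raw_view objects")
  }
  samp <- Reduce(intersect, lapply(raw_views, `[[`, "sample_ids"))
  feat <- Reduce(intersect, lapply(raw_views, `[[`, "feature_ids"))
  if (length(samp) < 2 || length(feat) < 2) {
    per_s <- vapply(raw_views, function(v) length(v$sample_ids), integer(1))
    per_f <- vapply(raw_views, function(v) length(v$feature_ids), integer(1))
    stop2(sprintf(paste0("views share %d samples and %d features (need >= 2 of each); ",
                         "per-view counts: samples [%s], features [%s]"),
                  length(samp), length(feat),
                  paste(per_s, collapse = ", "), paste(per_f, collapse = ", ")))
  }
  samp <- sort(samp)
  feat <- sort(feat)
  if (is.null(view_names)) {
    view_names <- names(raw_views)
    if (is.null(view_names) || any(!nzchar(view_names))) {
      view_names <- paste0("view", seq_along(raw_views))
    }
  }
  mats <- lapply(raw_views, function(v) {
    m <- v$values[samp, feat, drop = FALSE]
    if (normalize) m <- minmax_rows(m)
    m
  })
  multiview_dataset(mats, sample_ids = samp, feature_ids = feat,
                    view_names = view_names)
}

#' Construct a multi-view dataset
#'
#' The container for `d` aligned non-negative matrices `X_I` (samples by
#' features) sharing both axes, as the shared-coefficient factorization
#' requires. Every entry must lie in \[0, 1\].
#'
#' @param views List of `d >= 1` numeric matrices with identical dimensions.
#' @param sample_ids,feature_ids Shared identifiers; default to the first
#'   view's dimnames.
#' @param view_names Names for the views.
#' @return An object of class `multiview_dataset` with elements `views`
#'   (named list of matrices), `sample_ids`, `feature_ids`, `view_names`.
#' @export
multiview_dataset <- function(views, sample_ids = NULL, feature_ids = NULL,
                              view_names = names(views)) {
  if (!is.list(views) || !length(views)) stop2("`views` must be a non-empty list")
  d <- length(views)
  dims <- dim(views[[1]])
  for (i in seq_len(d)) {
    assert_matrix(views[[i]], sprintf("views[[%d]]", i))
    if (!identical(dim(views[[i]]), dims)) {
      stop2("all views must have identical dimensions (same samples and features)")
    }
    if (any(views[[i]] < 0) || any(views[[i]] > 1)) {
      stop2(sprintf("views[[%d]] has entries outside [0, 1]; run minmax_rows() first", i))
    }
  }
  if (is.null(sample_ids)) sample_ids <- rownames(views[[1]])
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(dims[1]))
  if (is.null(feature_ids)) feature_ids <- colnames(views[[1]])
  if (is.null(feature_ids)) feature_ids <- paste0("feature", seq_len(dims[2]))
  if (length(sample_ids) != dims[1] || length(feature_ids) != dims[2]) {
    stop2("id lengths do not match view dimensions")
  }
  if (is.null(view_names) || any(!nzchar(view_names))) {
    view_names <- paste0("view", seq_len(d))
  }
  views <- lapply(views, function(m) {
    dimnames(m) <- list(sample_ids, feature_ids)
    m
  })
  names(views) <- view_names
  structure(list(views = views, sample_ids = as.character(sample_ids),
                 feature_ids = as.character(feature_ids),
                 view_names = as.character(view_names)),
            class = "multiview_dataset")
}

#' @export
print.multiview_dataset <- function(x, ...) {
  cat(sprintf("<multiview_dataset> %d view(s), %d samples x %d features\n",
              length(x$views), length(x$sample_ids), length(x$feature_ids)))
  cat("  views:", paste(x$view_names, collapse = ", "), "\n")
  invisible(x)
}

#' Write a multi-view dataset to a directory
#'
#' Each view is written as `<name>.csv` (full precision) together with a
#' `manifest.json` recording view names, dimensions and file paths.
#'
#' @param data A [multiview_dataset()].
#' @param dir Output directory (created if absent).
#' @param extra Optional named list merged into the manifest (e.g. the
#'   preprocessing applied or a ground-truth file path).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(data, dir, extra = list()) {
  stopifnot(inherits(data, "multiview_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in data$view_names) {
    f <- file.path(dir, paste0(nm, ".csv"))
    write_matrix_csv(data$views[[nm]], f)
    files[nm] <- basename(f)
  }
  manifest <- c(list(kind = "multiview_dataset",
                     view_names = data$view_names,
                     view_files = as.list(files),
                     n_samples = length(data$sample_ids),
                     n_features = length(data$feature_ids)),
                extra)
  path <- file.path(dir, "manifest.json")
  write_json_file(manifest, path)
  invisible(path)
}

#' Read a multi-view dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.json` and the view CSV files.
#' @return A [multiview_dataset()].
#' @export
read_dataset <- function(dir) {
  manifest <- read_json_file(file.path(dir, "manifest.json"))
  views <- lapply(manifest$view_names, function(nm) {
    read_matrix_csv(file.path(dir, manifest$view_files[[nm]]))
  })
  names(views) <- manifest$view_names
  multiview_dataset(views, view_names = manifest$view_names)
}
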