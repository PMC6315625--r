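#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == as.integer(x)
}

assert_count <- function(x, name) {
  if (!is_count(x)) stop2(sprintf("`%s` must be a single positive integer, got %s",
                                  name, deparse(x)))
  as.integer(x)
}

assert_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop2(sprintf("`%s` must be a numeric matrix", name))
  }
  if (any(!is.finite(x))) stop2(sprintf("`%s` contains non-finite values", name))
  x
}

assert_nonneg <- function(x, name) {
  assert_matrix(x, name)
  if (any(x < 0)) stop2(sprintf("`%s` must be entrywise non-negative", name))
  x
}

## Full-precision text serialization of matrices so that a write/read
## round-trip is bit-exact ("%.17g" is lossless for doubles).
write_matrix_csv <- function(x, path) {
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("row", seq_len(nrow(x)))
  cols <- colnames(x)
  if (is.null(cols)) cols <- paste0("col", seq_len(ncol(x)))
  header <- paste(c("", cols), collapse = ",")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(ids[i], sprintf("%.17g", x[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
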