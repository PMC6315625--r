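## Sample affinity graphs: symmetric K-nearest-neighbor adjacency and the
## graph Laplacian L = D - E used by the manifold regularizer.

#' Build a K-nearest-neighbor affinity graph over samples
#'
#' Edges are binary: `E[i, j] = 1` when sample `i` is among the `K` nearest
#' neighbors (Euclidean distance, self excluded) of sample `j` *or* vice
#' versa, so `E` is symmetric by construction. The degree matrix `D` holds the
#' row sums of `E` on its diagonal and the Laplacian is `L = D - E`, which is
#' positive semi-definite with zero row sums. Distance ties at the K-th
#' neighbor are broken by lower sample index, so duplicated points are
#' handled deterministically.
#'
#' @param points Numeric matrix, one sample per row (typically a preprocessed
#'   view of a [multiview_dataset()]).
#' @param K Number of neighbors, `1 <= K <= n - 1`.
#' @return An object of class `affinity_graph` with elements `E`, `D`, `L`
#'   (dense `n x n` matrices), `degrees` (the diagonal of `D`) and `K`.
#' @examples
#' g <- knn_adjacency(matrix(c(0, 1, 10), ncol = 1), K = 1)
#' g$E
#' @export
knn_adjacency <- function(points, K) {
  points <- assert_matrix(points, "points")
  n <- nrow(points)
  if (n < 2) stop2("need at least 2 samples to build a graph")
  K <- assert_count(K, "K")
  if (K >= n) stop2(sprintf("K = %d must be < n = %d", K, n))
  dmat <- as.matrix(stats::dist(points))
  diag(dmat) <- Inf
  E <- matrix(0, n, n)
  for (i in seq_len(n)) {
    # order() breaks distance ties by lower index
    nbr <- order(dmat[i, ])[seq_len(K)]
    E[i, nbr] <- 1
  }
  E <- pmax(E, t(E))  # the symmetric "or" rule
  diag(E) <- 0
  deg <- rowSums(E)
  D <- diag(deg, n)
  L <- D - E
  ids <- rownames(points)
  if (!is.null(ids)) dimnames(E) <- dimnames(D) <- dimnames(L) <- list(ids, ids)
  structure(list(E = E, D = D, L = L, degrees = deg, K = K),
            class = "affinity_graph")
}

#' @export
print.affinity_graph <- function(x, ...) {
  cat(sprintf("<affinity_graph> %d nodes, %d edges, K = %d\n",
              nrow(x$E), sum(x$E) / 2, x$K))
  invisible(x)
}

#' Laplacian quadratic form tr(F' L F)
#'
#' Measures how strongly the rows of `F` vary across graph edges; it equals
#' the edge sum `0.5 * sum_ij E[i, j] * ||F[i, ] - F[j, ]||^2` and is zero
#' whenever `F` is constant over each connected component.
#'
#' @param L A Laplacian matrix or an `affinity_graph`.
#' @param F_mat Numeric matrix with one row per graph node.
#' @return A non-negative scalar.
#' @export
laplacian_quadratic <- function(L, F_mat) {
  if (inherits(L, "affinity_graph")) L <- L$L
  L <- assert_matrix(L, "L")
  F_mat <- assert_matrix(F_mat, "F_mat")
  if (nrow(F_mat) != nrow(L)) {
    stop2(sprintf("F has %d rows but L is %d x %d",
                  nrow(F_mat), nrow(L), ncol(L)))
  }
  sum(F_mat * (L %*% F_mat))
}

#' Export graph edges as a tab-separated edge list
#'
#' Writes one line per undirected edge (`i < j`) with columns `i`, `j`,
#' `weight`, using sample identifiers when the graph has them.
#'
#' @param graph An `affinity_graph`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "affinity_graph"))
  E <- graph$E
  idx <- which(upper.tri(E) & E > 0, arr.ind = TRUE)
  ids <- rownames(E)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(E)))
  df <- data.frame(i = ids[idx[, 1]], j = ids[idx[, 2]],
                   weight = E[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
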