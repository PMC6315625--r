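# Independent oracles used across the suite. These deliberately avoid the
# package's own linear-algebra shortcuts: objectives are computed elementwise,
# pair metrics by explicit pair enumeration, accuracy by permutation
# enumeration, and the reference single-view NMF is written out by hand.

# Classical two-factor NMF with multiplicative updates, same initialization
# scheme (seeded uniform W then H) and denominator guard as the package
# solvers use.
reference_nmf <- function(X, k, seed, max_iter, eps = 1e-10) {
  n <- nrow(X); m <- ncol(X)
  set.seed(seed)
  W <- matrix(runif(n * k), n, k)
  H <- matrix(runif(k * m), k, m)
  history <- numeric(max_iter + 1)
  history[1] <- sum((X - W %*% H)^2)
  for (it in seq_len(max_iter)) {
    # crossprod/tcrossprod keep the comparison with the package bitwise
    # (plain t()-and-%*% chains route through a different BLAS kernel)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    H <- H * crossprod(W, X) / (crossprod(W) %*% H + eps)
    history[it + 1] <- sum((X - W %*% H)^2)
  }
  list(W = W, H = H, history = history)
}

# Elementwise objective of the shared-coefficient model (loops, no tricks).
oracle_objective_gmvnmf <- function(X_list, L_list, W, U_list, V, lambdas) {
  lambdas <- rep_len(lambdas, length(X_list))
  total <- 0
  for (I in seq_along(X_list)) {
    approx <- W %*% U_list[[I]] %*% V
    for (i in seq_len(nrow(approx))) {
      for (j in seq_len(ncol(approx))) {
        total <- total + (X_list[[I]][i, j] - approx[i, j])^2
      }
    }
    if (lambdas[I] > 0) {
      L <- L_list[[I]]
      reg <- 0
      for (a in seq_len(ncol(W))) {
        reg <- reg + drop(t(W[, a]) %*% L %*% W[, a])
      }
      total <- total + lambdas[I] * reg
    }
  }
  total
}

# Trace expansion of the same objective: per view,
# tr(X'X) - 2 tr(X' W U V) + tr(V' U' W' W U V) + lambda tr(W' L W).
trace_objective_gmvnmf <- function(X_list, L_list, W, U_list, V, lambdas) {
  lambdas <- rep_len(lambdas, length(X_list))
  total <- 0
  for (I in seq_along(X_list)) {
    X <- X_list[[I]]; U <- U_list[[I]]
    total <- total +
      sum(diag(crossprod(X))) -
      2 * sum(diag(crossprod(X, W %*% U %*% V))) +
      sum(diag(t(V) %*% t(U) %*% crossprod(W) %*% U %*% V))
    if (lambdas[I] > 0) {
      total <- total + lambdas[I] * sum(diag(t(W) %*% L_list[[I]] %*% W))
    }
  }
  total
}

# Edge-sum form of the Laplacian quadratic: 0.5 sum_ij E_ij ||F_i - F_j||^2.
oracle_edge_sum <- function(E, F_mat) {
  total <- 0
  n <- nrow(E)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (E[i, j] != 0) {
        total <- total + E[i, j] * sum((F_mat[i, ] - F_mat[j, ])^2)
      }
    }
  }
  total / 2
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# Accuracy by exhaustive enumeration of label permutations.
oracle_accuracy <- function(true_labels, predicted_labels) {
  s <- as.integer(factor(true_labels))
  r <- as.integer(factor(predicted_labels))
  q <- max(max(s), max(r))
  best <- 0
  for (perm in all_permutations(seq_len(q))) {
    best <- max(best, sum(s == perm[r]))
  }
  best / length(s)
}

# Pairwise metrics by explicit enumeration of all unordered pairs.
oracle_pairwise <- function(true_labels, predicted_labels) {
  n <- length(true_labels)
  tp <- fn <- fp <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_t <- true_labels[i] == true_labels[j]
      same_p <- predicted_labels[i] == predicted_labels[j]
      if (same_t && same_p) tp <- tp + 1
      if (same_t && !same_p) fn <- fn + 1
      if (!same_t && same_p) fp <- fp + 1
    }
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (recall > 0 && precision > 0) 2 / (1 / recall + 1 / precision) else 0
  c(recall = recall, precision = precision, f_measure = f)
}

# Brute-force minimum-cost assignment by permutation enumeration.
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  for (perm in all_permutations(seq_len(n))) {
    best <- min(best, sum(cost[cbind(seq_len(n), perm)]))
  }
  best
}

# Small random multi-view problem for solver property runs.
random_views <- function(seed, n = 10, m = 12, d = 2) {
  set.seed(seed)
  lapply(seq_len(d), function(i) matrix(runif(n * m), n, m))
}

# Planted exactly-factorizable problem: X_I = W* U_I* V*.
planted_problem <- function(seed, n = 30, m = 40, d = 2, k = 3, r = 2) {
  set.seed(seed)
  W <- matrix(runif(n * k), n, k)
  U <- lapply(seq_len(d), function(i) matrix(runif(k * r), k, r))
  V <- matrix(runif(r * m), r, m)
  list(X = lapply(U, function(u) W %*% u %*% V), W = W, U = U, V = V)
}

max_rel_increase <- function(history) {
  if (length(history) < 2) return(0)
  max(diff(history) / pmax(abs(history[-length(history)]), 1e-12))
}
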