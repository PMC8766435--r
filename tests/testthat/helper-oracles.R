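# Independent brute-force oracles used to validate the package's
# primitives. These deliberately share no code with the implementation.

# two-pass Pearson correlation of two vectors
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_correlation_matrix <- function(A) {
  K <- ncol(A)
  P <- diag(K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    P[i, j] <- oracle_pearson(A[, i], A[, j])
  }
  P
}

# ARI by explicit pair counting over all C(n,2) pairs
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]
    same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    else if (!same_a && !same_b) s00 <- s00 + 1
    else if (same_a) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  num <- 2 * (s11 * s00 - s10 * s01)
  den <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (den == 0) 1 else num / den
}

# marker sensitivity by direct counting over cells
oracle_sensitivity <- function(X, y) {
  types <- levels(factor(y))
  Sen <- matrix(0, nrow(X), length(types),
                dimnames = list(rownames(X), types))
  for (g in seq_len(nrow(X))) {
    expressing <- which(X[g, ] > 0)
    if (length(expressing) == 0) next
    for (k in seq_along(types)) {
      Sen[g, k] <- sum(y[expressing] == types[k]) / length(expressing)
    }
  }
  Sen
}

# O(K^3) agglomerative complete-linkage clustering on the columns of A;
# returns merge heights and the leaf set of every internal node
oracle_complete_linkage <- function(A) {
  K <- ncol(A)
  D <- as.matrix(stats::dist(t(A)))
  clusters <- as.list(colnames(A))
  heights <- numeric(0)
  merged_sets <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- max(D[clusters[[i]], clusters[[j]], drop = FALSE])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    merged <- c(clusters[[i]], clusters[[j]])
    heights <- c(heights, best[1])
    merged_sets <- c(merged_sets, list(sort(merged)))
    clusters <- c(clusters[-c(i, j)], list(merged))
  }
  list(heights = heights, sets = merged_sets)
}

# leaf sets of every internal node of a lineage tree, sorted for comparison
tree_node_sets <- function(node) {
  if (isTRUE(node$leaf)) return(list())
  c(tree_node_sets(node$left), tree_node_sets(node$right),
    list(sort(node$types)))
}

# Welch t statistic per gene between two cell groups
oracle_welch_t <- function(X, in_right) {
  apply(X, 1, function(v) {
    a <- v[!in_right]; b <- v[in_right]
    se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    if (se == 0) 0 else (mean(b) - mean(a)) / se
  })
}
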