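#' Per-type mean expression profiles
#'
#' Averages expression over the cells of each cell type, giving the
#' genes x types profile matrix whose column correlations drive the choice
#' between the flat and hierarchical classifiers.
#'
#' @param X expression matrix (genes x cells).
#' @param y factor of cell-type labels, one per column of `X`.
#' @return numeric matrix, genes x K, columns named by cell type.
#' @export
mean_profiles <- function(X, y) {
  X <- validate_expression(X)
  y <- align_labels(y, X)
  counts <- table(y)
  if (any(counts == 0L)) {
    stop("cell types with zero cells: ",
         paste(names(counts)[counts == 0L], collapse = ", "))
  }
  A <- unclass(X) %*% one_hot(y)
  sweep(A, 2L, as.numeric(counts), "/")
}

align_labels <- function(y, X) {
  if (length(y) != ncol(X)) {
    stop("label vector length ", length(y), " does not match ", ncol(X), " cells")
  }
  y <- as.factor(y)
  if (!is.null(names(y)) && !is.null(colnames(X))) {
    if (!setequal(names(y), colnames(X))) {
      stop("label names do not match matrix cell identifiers")
    }
    y <- y[colnames(X)]
  } else {
    names(y) <- colnames(X)
  }
  droplevels(y)
}

#' Pearson correlation between cell-type profiles
#'
#' @param A profile matrix from [mean_profiles()] (genes x K, K >= 2,
#'   G >= 2). A constant profile column has undefined correlations and is
#'   an error naming the type.
#' @return symmetric K x K correlation matrix with unit diagonal.
#' @export
profile_correlation <- function(A) {
  if (ncol(A) < 2L) stop("need at least two cell types")
  if (nrow(A) < 2L) stop("need at least two genes to correlate profiles")
  sds <- apply(A, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant mean profile for cell type(s): ",
         paste(colnames(A)[sds == 0], collapse = ", "))
  }
  P <- stats::cor(A, method = "pearson")
  diag(P) <- 1
  P
}

#' Choose between flat and hierarchical annotation
#'
#' The hierarchical classifier is engaged when any pair of cell types has a
#' profile correlation at or above the threshold `tau` (inclusive); with no
#' highly correlated pair, a single multi-class feed-forward network
#' suffices.
#'
#' @param P correlation matrix from [profile_correlation()].
#' @param tau threshold in (0, 1]; default 0.95.
#' @return object of class `"strategy_decision"`: list with `mode`
#'   (`"flat"` or `"hierarchical"`), `tau`, `max_offdiag`, and the most
#'   correlated type pair.
#' @export
select_strategy <- function(P, tau = 0.95) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1) {
    stop("tau must lie in (0, 1]")
  }
  off <- P
  diag(off) <- -Inf
  max_off <- max(off)
  idx <- which(off == max_off, arr.ind = TRUE)[1L, ]
  structure(
    list(
      mode = if (max_off >= tau) "hierarchical" else "flat",
      tau = tau,
      max_offdiag = max_off,
      top_pair = c(rownames(P)[idx[1L]], colnames(P)[idx[2L]])
    ),
    class = "strategy_decision"
  )
}

#' @export
print.strategy_decision <- function(x, ...) {
  cat(sprintf("strategy: %s (max off-diagonal profile correlation %.4f %s tau = %.2f)\n",
              x$mode, x$max_offdiag,
              if (x$max_offdiag >= x$tau) ">=" else "<", x$tau))
  cat(sprintf("most correlated pair: %s / %s\n", x$top_pair[1L], x$top_pair[2L]))
  invisible(x)
}
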