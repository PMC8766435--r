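#' Accurately assigned rate
#'
#' Proportion of cells whose predicted label exactly matches the true
#' label (label names must match; this is the supervised score).
#'
#' @param pred,truth label vectors of equal length.
#' @return scalar in `[0, 1]`.
#' @export
annotation_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("prediction and truth have different lengths (",
         length(pred), " vs ", length(truth), ")")
  }
  mean(as.character(pred) == as.character(truth))
}

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two partitions,
#' computed from the contingency table:
#' `(sum C(n_ij,2) - E) / (0.5 * (sum C(a_i,2) + sum C(b_j,2)) - E)`
#' with `E` the expectation under random permutation. Invariant to
#' relabeling of either vector; 1 for identical partitions, near 0 for
#' unrelated ones. When both partitions are single clusters (or both are
#' all singletons) the index is defined as 1.
#'
#' @param pred,truth label vectors of equal length, n >= 2.
#' @return scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("inputs have different lengths")
  n <- length(pred)
  if (n < 2L) stop("need at least 2 cells")
  tab <- table(pred, truth)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Score predictions against truth
#'
#' @param pred,truth label vectors of equal length.
#' @return object of class `"evaluation_report"`: `accuracy`, `ari`, and
#'   the truth x prediction `confusion` count table.
#' @export
evaluate_annotation <- function(pred, truth) {
  structure(list(
    accuracy = annotation_accuracy(pred, truth),
    ari = adjusted_rand_index(pred, truth),
    confusion = table(truth = as.character(truth), pred = as.character(pred)),
    n = length(pred)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("n = %d cells | accurately assigned rate = %.4f | ARI = %.4f\n",
              x$n, x$accuracy, x$ari))
  print(x$confusion)
  invisible(x)
}
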