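#' Build the cell-lineage tree
#'
#' Complete-linkage agglomerative clustering of the cell-type mean
#' profiles (Euclidean distance between profile columns). The resulting
#' binary tree has one leaf per cell type and K-1 internal nodes; each
#' internal node later receives a feature list and a binary classifier.
#' `hclust` merge order is deterministic for a given profile matrix, with
#' distance ties resolved by the original column order.
#'
#' @param A profile matrix from [mean_profiles()], K >= 2 columns.
#' @return object of class `"lineage_tree"`: recursive node structure
#'   (`root`), the underlying `hclust`, and the leaf `types`.
#' @export
build_lineage_tree <- function(A) {
  if (ncol(A) < 2L) stop("need at least 2 cell types to build a lineage tree")
  hc <- stats::hclust(stats::dist(t(A), method = "euclidean"),
                      method = "complete")
  types <- colnames(A)
  nodes <- vector("list", nrow(hc$merge))
  pick <- function(ref) {
    if (ref < 0) list(leaf = TRUE, type = types[-ref], types = types[-ref])
    else nodes[[ref]]
  }
  for (i in seq_len(nrow(hc$merge))) {
    left <- pick(hc$merge[i, 1L])
    right <- pick(hc$merge[i, 2L])
    nodes[[i]] <- list(leaf = FALSE, id = paste0("node", i),
                       height = hc$height[i],
                       types = c(left$types, right$types),
                       left = left, right = right,
                       features = NULL, clf = NULL)
  }
  structure(list(root = nodes[[length(nodes)]], hclust = hc, types = types),
            class = "lineage_tree")
}

row_vars <- function(M) {
  rowSums((M - rowMeans(M))^2) / (ncol(M) - 1L)
}

count_internal_nodes <- function(node) {
  if (isTRUE(node$leaf)) return(0L)
  1L + count_internal_nodes(node$left) + count_internal_nodes(node$right)
}

#' Export the lineage tree as Newick text
#'
#' @param tree a [build_lineage_tree()] result.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to file).
#' @export
export_tree_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("cell-lineage tree: %d leaves, %d bifurcations\n",
              length(x$types), count_internal_nodes(x$root)))
  cat(export_tree_newick(x), "\n")
  invisible(x)
}

#' Marker-gene sensitivity table
#'
#' For gene g and cell type k, sensitivity is the fraction of cells
#' expressing g (value > 0) that belong to type k. A gene expressed in no
#' cell has sensitivity 0 for every type; for any expressed gene the
#' sensitivities sum to 1 across types. Genes with sensitivity above
#' `sen_threshold` are that type's specific markers, and types with more
#' than `nu1` markers are eligible for marker-based pre-assignment.
#'
#' @param X training expression matrix (raw or normalized; only
#'   positivity is used, which log1p library scaling preserves).
#' @param y training labels.
#' @param sen_threshold marker cut-off on sensitivity (default 0.95,
#'   strict `>`).
#' @param nu1 minimum marker count (strict `>`) for a type to be eligible.
#' @return object of class `"sensitivity_table"`: `Sen` (genes x types),
#'   `marker_sets` (named list of gene ids), `eligible_types`,
#'   `sen_threshold`, `nu1`.
#' @export
marker_sensitivity <- function(X, y, sen_threshold = 0.95, nu1 = 10L) {
  X <- validate_expression(X)
  y <- align_labels(y, X)
  if (nu1 < 0) stop("nu1 must be non-negative")
  expressed <- unclass(X) > 0
  n_expressing <- rowSums(expressed)
  num <- expressed %*% one_hot(y)
  Sen <- num / ifelse(n_expressing == 0, 1, n_expressing)
  marker_sets <- lapply(stats::setNames(colnames(Sen), colnames(Sen)),
                        function(k) rownames(Sen)[Sen[, k] > sen_threshold])
  eligible <- names(marker_sets)[vapply(marker_sets, length, 1L) > nu1]
  structure(list(Sen = Sen, marker_sets = marker_sets,
                 eligible_types = eligible,
                 sen_threshold = sen_threshold, nu1 = as.integer(nu1)),
            class = "sensitivity_table")
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat(sprintf("marker sensitivity: %d genes x %d types (Sen > %.2f, nu1 = %d)\n",
              nrow(x$Sen), ncol(x$Sen), x$sen_threshold, x$nu1))
  sizes <- vapply(x$marker_sets, length, 1L)
  cat("markers per type:",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  cat("eligible for pre-assignment:",
      if (length(x$eligible_types)) paste(x$eligible_types, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Marker-based pre-assignment of test cells
#'
#' A test cell is pre-assigned to type k when k is eligible (more than
#' `nu1` specific markers in the training data) and the cell expresses
#' strictly more than `nu2` of k's markers, and k is the only such type.
#' Cells qualifying for zero or for multiple types are deferred to the
#' lineage tree. Markers absent from the test gene space contribute
#' nothing.
#'
#' @param X1 test expression matrix.
#' @param sens a [marker_sensitivity()] table built on the training data.
#' @param nu2 marker-expression threshold (strict `>`, default 3).
#' @return character vector named by test cell id; `NA` marks cells
#'   deferred to the tree.
#' @export
marker_preassign <- function(X1, sens, nu2 = 3L) {
  X1 <- validate_expression(X1)
  if (nu2 < 0) stop("nu2 must be non-negative")
  assigned <- rep(NA_character_, ncol(X1))
  names(assigned) <- colnames(X1)
  if (length(sens$eligible_types) == 0L) return(assigned)
  qualifies <- vapply(sens$eligible_types, function(k) {
    mk <- intersect(sens$marker_sets[[k]], rownames(X1))
    if (length(mk) == 0L) return(rep(FALSE, ncol(X1)))
    colSums(unclass(X1)[mk, , drop = FALSE] > 0) > nu2
  }, logical(ncol(X1)))
  qualifies <- matrix(qualifies, ncol = length(sens$eligible_types),
                      dimnames = list(colnames(X1), sens$eligible_types))
  n_hits <- rowSums(qualifies)
  unique_hit <- which(n_hits == 1L)
  if (length(unique_hit)) {
    assigned[unique_hit] <-
      sens$eligible_types[max.col(qualifies[unique_hit, , drop = FALSE])]
  }
  assigned
}

#' Select bifurcation-specific features
#'
#' Ranks genes by the absolute moderated t-statistic (limma's
#' empirical-Bayes shrunken variance) contrasting the pooled cells of the
#' left branch against the pooled cells of the right branch, and returns
#' the top `min(M, G)` gene ids. Ties are broken by gene id for
#' determinism. When either branch has fewer than 2 cells the moderated
#' fit is undefined and ranking falls back to the absolute mean
#' difference, with a warning.
#'
#' @param X training expression matrix (normalized).
#' @param y training labels.
#' @param left_types,right_types cell types of the two branches.
#' @param M number of features to keep (default 1000).
#' @return character vector of gene ids, length `min(M, nrow(X))`.
#' @export
bifurcation_features <- function(X, y, left_types, right_types, M = 1000L) {
  X <- validate_expression(X)
  y <- align_labels(y, X)
  keep <- y %in% c(left_types, right_types)
  if (!any(y %in% left_types) || !any(y %in% right_types)) {
    stop("both branches need at least one training cell")
  }
  Xn <- unclass(X)[, keep, drop = FALSE]
  branch <- factor(ifelse(y[keep] %in% right_types, "right", "left"),
                   levels = c("left", "right"))
  if (min(table(branch)) < 2L) {
    warning("branch with < 2 cells; ranking by unmoderated mean difference")
    score <- abs(rowMeans(Xn[, branch == "left", drop = FALSE]) -
                   rowMeans(Xn[, branch == "right", drop = FALSE]))
  } else {
    design <- stats::model.matrix(~ branch)
    # constant genes carry no contrast; score 0 without entering the fit
    varying <- row_vars(Xn) > 0
    score <- numeric(nrow(Xn))
    if (any(varying)) {
      fit <- limma::eBayes(limma::lmFit(Xn[varying, , drop = FALSE], design))
      tstat <- abs(fit$t[, 2L])
      tstat[!is.finite(tstat)] <- 0
      score[varying] <- tstat
    }
  }
  ord <- order(-score, rownames(X), method = "radix")
  rownames(X)[ord][seq_len(min(as.integer(M), nrow(X)))]
}

#' Train the hierarchical annotator
#'
#' Fits one binary feed-forward network per bifurcation of the lineage
#' tree. Each node uses only the training cells whose type lies in its
#' leaf set, its own top-M feature list from [bifurcation_features()], and
#' binary cross-entropy with target 1 for right-branch cells. Also stores
#' the marker sensitivity table used for pre-assignment at prediction.
#'
#' @param X training expression matrix (normalized).
#' @param y training labels.
#' @param tree a [build_lineage_tree()] result.
#' @param spec [network_spec()] shared by all node networks.
#' @param config [train_config()]; each node derives its own seed from
#'   `config$seed` so node fits are independent and reproducible.
#' @param M features per bifurcation (default 1000).
#' @param sen_threshold,nu1 marker parameters, see [marker_sensitivity()].
#' @return object of class `"hierarchical_annotator"`.
#' @export
train_hierarchy <- function(X, y, tree, spec = network_spec("small"),
                            config = train_config(), M = 1000L,
                            sen_threshold = 0.95, nu1 = 10L) {
  X <- validate_expression(X)
  y <- align_labels(y, X)
  missing_types <- setdiff(tree$types, levels(y))
  if (length(missing_types)) {
    stop("tree types without training cells: ",
         paste(missing_types, collapse = ", "))
  }
  sens <- marker_sensitivity(X, y, sen_threshold = sen_threshold, nu1 = nu1)
  node_counter <- 0L
  fit_node <- function(node) {
    if (isTRUE(node$leaf)) return(node)
    node$left <- fit_node(node$left)
    node$right <- fit_node(node$right)
    node_counter <<- node_counter + 1L
    node_seed <- (config$seed + 7919L * node_counter) %% 2147483647L
    tryCatch({
      node$features <- bifurcation_features(X, y, node$left$types,
                                            node$right$types, M = M)
      keep <- y %in% node$types
      Xn <- expression_matrix(unclass(X)[node$features, keep, drop = FALSE],
                              normalized = is_normalized(X))
      ybin <- factor(ifelse(y[keep] %in% node$right$types, "right", "left"),
                     levels = c("left", "right"))
      names(ybin) <- colnames(Xn)
      clf <- build_network(length(node$features), 2L, spec = spec,
                           seed = node_seed, output = "sigmoid")
      node_config <- config
      node_config$seed <- node_seed
      node$clf <- train_network(clf, Xn, ybin, node_config)
      node
    }, error = function(e) {
      stop("training failed at ", node$id, " (",
           paste(node$left$types, collapse = "+"), " vs ",
           paste(node$right$types, collapse = "+"), "): ",
           conditionMessage(e), call. = FALSE)
    })
  }
  tree$root <- fit_node(tree$root)
  structure(list(tree = tree, sensitivity = sens, spec = spec,
                 config = config, M = as.integer(M),
                 class_order = sort(tree$types, method = "radix")),
            class = "hierarchical_annotator")
}

#' Predict cell types with the hierarchical annotator
#'
#' Two-stage exhaustive assignment. Cells expressing strictly more than
#' `nu2` specific markers of exactly one eligible type keep that label and
#' are never revisited. Every remaining cell is routed from the root to a
#' leaf by the node classifiers (right branch when the predicted
#' right-probability is >= 0.5) and receives the leaf's type, so the
#' output contains no unassigned cells and only training-set labels.
#'
#' @param h a trained [train_hierarchy()] annotator.
#' @param X1 test expression matrix (normalized like the training data).
#' @param nu2 marker-expression threshold for pre-assignment (default 3).
#' @return list with `labels` (factor named by cell id), `preassigned`
#'   (logical vector), and `n_preassigned`.
#' @export
predict_hierarchical <- function(h, X1, nu2 = 3L) {
  X1 <- validate_expression(X1)
  pre <- marker_preassign(X1, h$sensitivity, nu2 = nu2)
  labels <- pre
  route <- function(node, cells) {
    if (length(cells) == 0L) return(invisible(NULL))
    if (isTRUE(node$leaf)) {
      labels[cells] <<- node$type
      return(invisible(NULL))
    }
    Xsub <- expression_matrix(unclass(X1)[, cells, drop = FALSE],
                              normalized = is_normalized(X1))
    p_right <- as.numeric(predict_network(node$clf, Xsub)$probs)
    route(node$left, cells[p_right < 0.5])
    route(node$right, cells[p_right >= 0.5])
  }
  route(h$tree$root, names(pre)[is.na(pre)])
  stopifnot(!anyNA(labels))
  out <- factor(labels, levels = h$class_order)
  names(out) <- colnames(X1)
  list(labels = out, preassigned = !is.na(pre),
       n_preassigned = sum(!is.na(pre)))
}
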