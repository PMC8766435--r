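#' Train a cell-type annotator
#'
#' Full training path on in-memory matrices: per-type mean profiles, the
#' profile correlation matrix, strategy dispatch at threshold `tau`, then
#' either a single multi-class feed-forward network (flat mode) or the
#' marker-table-plus-lineage-tree hierarchical annotator. Expects
#' normalized input (see [normalize_expression()]); gene spaces of train
#' and test data should be intersected beforehand with
#' [intersect_genes()] — [annotate_cells()] does both for you.
#'
#' @param X0 training expression matrix (genes x cells, normalized).
#' @param y0 training labels (factor, >= 2 types).
#' @param tau correlation threshold for hierarchical dispatch
#'   (default 0.95).
#' @param force_mode `"auto"` (use the correlation rule), `"flat"`, or
#'   `"hierarchical"`.
#' @param spec [network_spec()] for all networks.
#' @param config [train_config()].
#' @param M features per bifurcation (hierarchical mode).
#' @param sen_threshold,nu1 marker parameters (hierarchical mode).
#' @return object of class `"cell_annotator"` holding the mode decision,
#'   the fitted model, and all parameters.
#' @export
train_annotator <- function(X0, y0, tau = 0.95,
                            force_mode = c("auto", "flat", "hierarchical"),
                            spec = network_spec("small"),
                            config = train_config(), M = 1000L,
                            sen_threshold = 0.95, nu1 = 10L) {
  force_mode <- match.arg(force_mode)
  X0 <- validate_expression(X0)
  y0 <- align_labels(y0, X0)
  if (nlevels(y0) < 2L) stop("training requires at least 2 cell types")
  A <- mean_profiles(X0, y0)
  P <- profile_correlation(A)
  decision <- select_strategy(P, tau = tau)
  mode <- if (force_mode == "auto") decision$mode else force_mode
  model <- if (mode == "flat") {
    clf <- build_network(nrow(X0), nlevels(y0), spec = spec,
                         seed = config$seed, output = "softmax")
    train_network(clf, X0, y0, config)
  } else {
    tree <- build_lineage_tree(A)
    train_hierarchy(X0, y0, tree, spec = spec, config = config, M = M,
                    sen_threshold = sen_threshold, nu1 = nu1)
  }
  structure(list(mode = mode, forced = force_mode != "auto",
                 decision = decision, profiles = A, correlation = P,
                 model = model, spec = spec, config = config,
                 tau = tau, M = as.integer(M),
                 sen_threshold = sen_threshold, nu1 = as.integer(nu1),
                 class_order = levels(y0)),
            class = "cell_annotator")
}

#' Predict cell types for a test matrix
#'
#' Every test cell receives exactly one training-set label (assignment is
#' exhaustive in both modes).
#'
#' @param object a trained [train_annotator()].
#' @param X1 test expression matrix (normalized like the training data).
#' @param nu2 marker-expression threshold for hierarchical
#'   pre-assignment.
#' @param ... unused.
#' @return list with `labels` (factor named by cell id), `mode`, and for
#'   hierarchical mode `n_preassigned`.
#' @export
predict.cell_annotator <- function(object, X1, nu2 = 3L, ...) {
  X1 <- validate_expression(X1)
  if (object$mode == "flat") {
    pr <- predict_network(object$model, X1)
    list(labels = pr$labels, mode = "flat", probs = pr$probs)
  } else {
    pr <- predict_hierarchical(object$model, X1, nu2 = nu2)
    list(labels = pr$labels, mode = "hierarchical",
         n_preassigned = pr$n_preassigned, preassigned = pr$preassigned)
  }
}

#' @export
print.cell_annotator <- function(x, ...) {
  cat(sprintf("cell annotator: %s mode%s, %d types, %d genes\n",
              x$mode, if (x$forced) " (forced)" else "",
              length(x$class_order), nrow(x$profiles)))
  print(x$decision)
  invisible(x)
}

#' One-call annotation of a test dataset
#'
#' Normalizes both matrices, intersects their gene spaces, trains the
#' dispatched annotator on the reference and labels every test cell.
#'
#' @param X0,y0 raw training matrix and labels.
#' @param X1 raw test matrix.
#' @param normalize_method `"lognorm"` or `"none"` (for pre-normalized
#'   input).
#' @param nu2 marker threshold at prediction.
#' @inheritParams train_annotator
#' @return list with `labels`, `annotator`, `report` (mode, correlation
#'   summary, per-type prediction counts, parameters).
#' @export
annotate_cells <- function(X0, y0, X1, tau = 0.95,
                           force_mode = c("auto", "flat", "hierarchical"),
                           spec = network_spec("small"),
                           config = train_config(), M = 1000L,
                           sen_threshold = 0.95, nu1 = 10L, nu2 = 3L,
                           normalize_method = c("lognorm", "none")) {
  normalize_method <- match.arg(normalize_method)
  force_mode <- match.arg(force_mode)
  X0 <- normalize_expression(X0, method = normalize_method)
  X1 <- normalize_expression(X1, method = normalize_method)
  both <- intersect_genes(X0, X1)
  ann <- train_annotator(both$train, y0, tau = tau, force_mode = force_mode,
                         spec = spec, config = config, M = M,
                         sen_threshold = sen_threshold, nu1 = nu1)
  pred <- predict(ann, both$test, nu2 = nu2)
  report <- list(
    mode = ann$mode,
    forced = ann$forced,
    max_offdiag_correlation = ann$decision$max_offdiag,
    tau = tau,
    n_train = ncol(both$train), n_test = ncol(both$test),
    n_genes = nrow(both$train),
    n_preassigned = pred$n_preassigned %||% 0L,
    predicted_counts = as.list(table(pred$labels)),
    parameters = list(model_size = spec$size_name, epochs = config$epochs,
                      batch_size = config$batch_size,
                      learning_rate = config$learning_rate,
                      seed = config$seed, M = M,
                      sen_threshold = sen_threshold,
                      nu1 = nu1, nu2 = nu2)
  )
  list(labels = pred$labels, annotator = ann, report = report)
}

#' File-based annotation run
#'
#' Reads the training matrix + labels and the test matrix, runs
#' [annotate_cells()], writes a predictions TSV
#' (`cell_id<TAB>predicted_label`) and a JSON run report next to it. Any
#' stage failure removes partial outputs.
#'
#' @param train_matrix,train_labels,test_matrix input paths (dense
#'   TSV/CSV or `.mtx` with sidecars).
#' @param out_prefix output path prefix; writes
#'   `<out_prefix>.predictions.tsv` and `<out_prefix>.report.json`.
#' @param genes_as orientation of dense input files.
#' @inheritParams annotate_cells
#' @return the [annotate_cells()] result, invisibly.
#' @export
run_annotation <- function(train_matrix, train_labels, test_matrix,
                           out_prefix, tau = 0.95,
                           force_mode = c("auto", "flat", "hierarchical"),
                           spec = network_spec("small"),
                           config = train_config(), M = 1000L,
                           sen_threshold = 0.95, nu1 = 10L, nu2 = 3L,
                           normalize_method = c("lognorm", "none"),
                           genes_as = c("rows", "cols")) {
  pred_path <- paste0(out_prefix, ".predictions.tsv")
  report_path <- paste0(out_prefix, ".report.json")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(c(pred_path, report_path))
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  X0 <- stage("read-train", read_expression(train_matrix, genes_as = genes_as))
  y0 <- stage("read-labels", read_labels(train_labels, colnames(X0)))
  X1 <- stage("read-test", read_expression(test_matrix, genes_as = genes_as))
  res <- stage("annotate", annotate_cells(
    X0, y0, X1, tau = tau, force_mode = force_mode, spec = spec,
    config = config, M = M, sen_threshold = sen_threshold,
    nu1 = nu1, nu2 = nu2, normalize_method = normalize_method))
  stage("write", {
    write_labels(res$labels, pred_path)
    jsonlite::write_json(res$report, report_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  })
  invisible(res)
}
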