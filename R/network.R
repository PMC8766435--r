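#' Network size specification
#'
#' Three stock architectures for the dense classifier. Hidden widths are
#' 64 (small), 64,128 (medium) and 64,128,256 (big); all hidden layers use
#' ReLU activation and the output layer is softmax (multi-class) or sigmoid
#' (binary lineage-tree nodes).
#'
#' @param size `"small"`, `"medium"` or `"big"`.
#' @return list with `size_name` and integer `hidden_widths`.
#' @export
network_spec <- function(size = c("small", "medium", "big")) {
  size <- match.arg(size)
  widths <- switch(size,
    small = 64L,
    medium = c(64L, 128L),
    big = c(64L, 128L, 256L)
  )
  list(size_name = size, hidden_widths = widths)
}

#' Training configuration
#'
#' Mini-batch RMSprop with a fixed epoch budget. Defaults are the
#' framework-standard RMSprop settings; all are user-tunable.
#'
#' @param batch_size cells per mini-batch (>= 1).
#' @param epochs passes over the training set (>= 1).
#' @param learning_rate RMSprop step size (> 0).
#' @param rho RMSprop moving-average decay for squared gradients.
#' @param epsilon RMSprop denominator stabilizer.
#' @param seed integer seed; fixes weight initialization noise-free batch
#'   order, so identical configurations reproduce identical models.
#' @param validation_fraction fraction of training cells held out to track
#'   a validation loss trace (0 disables; held-out cells are not trained on).
#' @return list of class `"train_config"`.
#' @export
train_config <- function(batch_size = 128L, epochs = 30L,
                         learning_rate = 1e-3, rho = 0.9, epsilon = 1e-7,
                         seed = 1L, validation_fraction = 0) {
  stopifnot(batch_size >= 1L, learning_rate > 0,
            rho > 0, rho < 1, epsilon > 0,
            validation_fraction >= 0, validation_fraction < 1)
  if (!is.numeric(epochs) || epochs < 1L) stop("epochs must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, rho = rho, epsilon = epsilon,
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction),
            class = "train_config")
}

relu <- function(z) pmax(z, 0)

#' Numerically stable softmax
#'
#' Row-wise softmax with max-subtraction, so adding a constant to every
#' input leaves the output unchanged and large inputs do not overflow.
#'
#' @param eta numeric vector (one set of scores) or n x K matrix of scores.
#' @return probabilities of the same shape; rows sum to 1.
#' @export
softmax <- function(eta) {
  if (is.null(dim(eta))) {
    e <- exp(eta - max(eta))
    return(e / sum(e))
  }
  e <- exp(eta - apply(eta, 1L, max))
  e / rowSums(e)
}

clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Categorical cross-entropy loss
#'
#' Mean over cells of minus the log-probability assigned to the true
#' class. Probabilities are clamped at 1e-12 so a zero at the true class
#' yields a large finite loss rather than infinity.
#'
#' @param probs n x K matrix of predicted class probabilities (rows sum to 1).
#' @param labels one-hot n x K matrix, or a factor of length n whose levels
#'   match `colnames(probs)` order.
#' @return non-negative scalar loss.
#' @export
categorical_cross_entropy <- function(probs, labels) {
  probs <- rbind(probs)
  if (is.factor(labels) || is.character(labels)) {
    labels <- one_hot(factor(labels, levels = colnames(probs) %||%
                               levels(factor(labels))))
  }
  labels <- rbind(labels)
  stopifnot(identical(dim(probs), dim(labels)))
  -mean(log(clamp_prob(probs))[labels == 1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

one_hot <- function(y) {
  y <- as.factor(y)
  Y <- matrix(0, length(y), nlevels(y), dimnames = list(names(y), levels(y)))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

#' Binary cross-entropy loss
#'
#' Used at lineage-tree bifurcations, where the target is 1 for cells
#' belonging to the right branch. Equals the categorical cross-entropy of
#' the equivalent two-class problem.
#'
#' @param probs predicted probabilities of the positive (right) class.
#' @param targets 0/1 vector of the same length.
#' @return non-negative scalar loss.
#' @export
binary_cross_entropy <- function(probs, targets) {
  stopifnot(length(probs) == length(targets), all(targets %in% c(0, 1)))
  p <- clamp_prob(probs)
  -mean(targets * log(p) + (1 - targets) * log(1 - p))
}

#' Build an untrained dense classifier
#'
#' Fully connected ReLU stack with widths from [network_spec()] and a
#' softmax (`output = "softmax"`, K classes) or single-unit sigmoid
#' (`output = "sigmoid"`) head. Weights use seeded uniform Glorot
#' initialization; the same seed reproduces identical weights.
#'
#' @param n_features number of input genes.
#' @param n_classes number of output classes (>= 2 for softmax; forced to
#'   1 output unit for sigmoid).
#' @param spec a [network_spec()].
#' @param seed integer seed for the initial weights.
#' @param output output head type.
#' @return object of class `"ff_classifier"` (untrained).
#' @export
build_network <- function(n_features, n_classes, spec = network_spec("small"),
                          seed = 1L, output = c("softmax", "sigmoid")) {
  output <- match.arg(output)
  stopifnot(n_features >= 1L)
  if (output == "softmax" && n_classes < 2L) {
    stop("softmax head needs at least 2 classes")
  }
  out_units <- if (output == "sigmoid") 1L else as.integer(n_classes)
  dims <- c(as.integer(n_features), spec$hidden_widths, out_units)
  set.seed(as.integer(seed))
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    limit <- sqrt(6 / (dims[l] + dims[l + 1L]))
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -limit, limit),
                     dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  structure(list(W = W, b = b, dims = dims, output = output,
                 spec = spec, seed = as.integer(seed),
                 gene_order = NULL, class_order = NULL,
                 loss_trace = NULL, trained = FALSE),
            class = "ff_classifier")
}

# Forward pass. X: cells x features. Returns activations (post-ReLU) per
# hidden layer and output probabilities.
nn_forward <- function(clf, X) {
  L <- length(clf$W)
  A <- vector("list", L - 1L)
  cur <- X
  for (l in seq_len(L - 1L)) {
    cur <- relu(sweep(cur %*% clf$W[[l]], 2L, clf$b[[l]], "+"))
    A[[l]] <- cur
  }
  eta <- sweep(cur %*% clf$W[[L]], 2L, clf$b[[L]], "+")
  probs <- if (clf$output == "softmax") softmax(eta) else 1 / (1 + exp(-eta))
  list(activations = A, probs = probs)
}

# Loss and analytic gradients for one batch. X: cells x features; Y:
# one-hot matrix (softmax) or 0/1 column vector (sigmoid). Gradient of the
# mean cross-entropy w.r.t. every weight and bias.
nn_gradients <- function(clf, X, Y) {
  fw <- nn_forward(clf, X)
  n <- nrow(X)
  L <- length(clf$W)
  loss <- if (clf$output == "softmax") {
    categorical_cross_entropy(fw$probs, Y)
  } else {
    binary_cross_entropy(as.numeric(fw$probs), as.numeric(Y))
  }
  # softmax+CE and sigmoid+BCE share the same output-layer gradient form
  delta <- (fw$probs - Y) / n
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in L:1) {
    Aprev <- if (l > 1L) fw$activations[[l - 1L]] else X
    gW[[l]] <- crossprod(Aprev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(clf$W[[l]])) * (fw$activations[[l - 1L]] > 0)
    }
  }
  list(loss = loss, gW = gW, gb = gb)
}

#' Train a dense classifier
#'
#' Mini-batch RMSprop on categorical (softmax head) or binary (sigmoid
#' head) cross-entropy. Batch composition is reshuffled every epoch from
#' the configuration seed, so training is fully deterministic. The
#' per-epoch mean training loss is recorded in `loss_trace`.
#'
#' @param clf untrained classifier from [build_network()].
#' @param X expression matrix (genes x cells), normalized.
#' @param y factor of labels (softmax: K levels in `class_order`; sigmoid:
#'   2 levels, the second level being the positive class) or a 0/1 vector.
#' @param config a [train_config()].
#' @return trained `"ff_classifier"` with `gene_order`, `class_order`,
#'   `loss_trace` (and `val_loss_trace` when a validation split is used).
#' @export
train_network <- function(clf, X, y, config = train_config()) {
  X <- validate_expression(X)
  if (!is_normalized(X)) {
    warning("training on a matrix not flagged as normalized")
  }
  if (clf$dims[1L] != nrow(X)) {
    stop("network expects ", clf$dims[1L], " features but matrix has ",
         nrow(X), " genes")
  }
  if (clf$output == "softmax") {
    y <- align_labels(y, X)
    if (nlevels(y) != clf$dims[length(clf$dims)]) {
      stop("network has ", clf$dims[length(clf$dims)], " outputs but labels have ",
           nlevels(y), " levels")
    }
    class_order <- levels(y)
    Yfull <- one_hot(y)
  } else {
    if (is.factor(y)) {
      if (nlevels(y) != 2L) stop("binary head needs exactly 2 label levels")
      class_order <- levels(y)
      Yfull <- matrix(as.numeric(as.integer(y) == 2L), ncol = 1L)
    } else {
      stopifnot(all(y %in% c(0, 1)), length(y) == ncol(X))
      class_order <- c("0", "1")
      Yfull <- matrix(as.numeric(y), ncol = 1L)
    }
  }
  Xt <- t(unclass(X))  # cells x genes
  n_all <- nrow(Xt)
  set.seed(config$seed)
  val_idx <- integer(0)
  if (config$validation_fraction > 0) {
    n_val <- max(1L, floor(config$validation_fraction * n_all))
    val_idx <- sample.int(n_all, n_val)
  }
  tr_idx <- setdiff(seq_len(n_all), val_idx)
  if (length(tr_idx) < 1L) stop("no training cells left after validation split")

  cW <- lapply(clf$W, function(w) w * 0)
  cb <- lapply(clf$b, function(v) v * 0)
  L <- length(clf$W)
  trace <- numeric(config$epochs)
  val_trace <- if (length(val_idx)) numeric(config$epochs) else NULL

  for (ep in seq_len(config$epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    splits <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (batch in splits) {
      g <- nn_gradients(clf, Xt[batch, , drop = FALSE],
                        Yfull[batch, , drop = FALSE])
      if (!is.finite(g$loss)) {
        stop("non-finite training loss at epoch ", ep,
             "; reduce the learning rate")
      }
      ep_loss <- ep_loss + g$loss * length(batch)
      for (l in seq_len(L)) {
        cW[[l]] <- config$rho * cW[[l]] + (1 - config$rho) * g$gW[[l]]^2
        cb[[l]] <- config$rho * cb[[l]] + (1 - config$rho) * g$gb[[l]]^2
        clf$W[[l]] <- clf$W[[l]] - config$learning_rate * g$gW[[l]] /
          (sqrt(cW[[l]]) + config$epsilon)
        clf$b[[l]] <- clf$b[[l]] - config$learning_rate * g$gb[[l]] /
          (sqrt(cb[[l]]) + config$epsilon)
      }
    }
    trace[ep] <- ep_loss / length(ord)
    if (length(val_idx)) {
      fw <- nn_forward(clf, Xt[val_idx, , drop = FALSE])
      val_trace[ep] <- if (clf$output == "softmax") {
        categorical_cross_entropy(fw$probs, Yfull[val_idx, , drop = FALSE])
      } else {
        binary_cross_entropy(as.numeric(fw$probs), as.numeric(Yfull[val_idx, ]))
      }
    }
  }
  clf$gene_order <- rownames(X)
  clf$class_order <- class_order
  clf$loss_trace <- trace
  clf$val_loss_trace <- val_trace
  clf$config <- config
  clf$trained <- TRUE
  clf
}

#' Predict cell types with a trained dense classifier
#'
#' The test matrix is reordered to the classifier's training gene order;
#' training genes missing from the test data are imputed as zero rows
#' (with a warning giving the count). Every cell receives exactly one
#' label: the argmax of its softmax row, ties broken toward the lowest
#' class index. The sigmoid head returns the positive-class probability
#' and labels at the 0.5 threshold (ties to the positive class).
#'
#' @param clf trained classifier.
#' @param X expression matrix (genes x cells), normalized like the
#'   training data.
#' @return list with `labels` (factor named by cell id) and `probs`
#'   (cells x classes matrix).
#' @export
predict_network <- function(clf, X) {
  if (!isTRUE(clf$trained)) stop("classifier has not been trained")
  X <- validate_expression(X)
  Xa <- align_to_genes(X, clf$gene_order)
  fw <- nn_forward(clf, t(Xa))
  probs <- fw$probs
  if (clf$output == "softmax") {
    colnames(probs) <- clf$class_order
    lab <- clf$class_order[max.col(probs, ties.method = "first")]
  } else {
    colnames(probs) <- clf$class_order[2L]
    lab <- clf$class_order[ifelse(as.numeric(probs) >= 0.5, 2L, 1L)]
  }
  rownames(probs) <- colnames(X)
  labels <- factor(lab, levels = clf$class_order)
  names(labels) <- colnames(X)
  list(labels = labels, probs = probs)
}

# Subset/reorder X's rows to `genes`; absent genes become zero rows.
align_to_genes <- function(X, genes) {
  present <- intersect(genes, rownames(X))
  if (length(present) == 0L) {
    stop("test matrix shares no genes with the classifier's features")
  }
  n_missing <- length(genes) - length(present)
  out <- matrix(0, length(genes), ncol(X),
                dimnames = list(genes, colnames(X)))
  out[present, ] <- unclass(X)[present, , drop = FALSE]
  if (n_missing > 0L) {
    warning(n_missing, " training gene(s) absent from test data; imputed as zero")
  }
  out
}

#' @export
print.ff_classifier <- function(x, ...) {
  cat(sprintf("feed-forward classifier (%s): %s -> %s head, %s\n",
              x$spec$size_name,
              paste(x$dims, collapse = " -> "), x$output,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  if (isTRUE(x$trained)) {
    cat(sprintf("final training loss %.4f after %d epochs\n",
                utils::tail(x$loss_trace, 1L), length(x$loss_trace)))
  }
  invisible(x)
}
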