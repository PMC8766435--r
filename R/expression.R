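#' Construct and validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix with genes as rows and
#' cells as columns. Row names are gene identifiers, column names are cell
#' identifiers; both must be unique and non-empty. Entries are non-negative
#' (raw counts or normalized values). The logical attribute `"normalized"`
#' records whether [normalize_expression()] has been applied.
#'
#' @param values numeric matrix, genes x cells.
#' @param gene_ids character vector of length `nrow(values)`; defaults to
#'   existing row names.
#' @param cell_ids character vector of length `ncol(values)`; defaults to
#'   existing column names.
#' @param normalized logical flag, `TRUE` for already-normalized values.
#' @return validated numeric matrix with the `"normalized"` attribute set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("expression matrix requires gene and cell identifiers")
  }
  rownames(values) <- as.character(gene_ids)
  colnames(values) <- as.character(cell_ids)
  attr(values, "normalized") <- isTRUE(normalized)
  validate_expression(values)
}

validate_expression <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("expression data must be a numeric matrix")
  }
  if (nrow(X) < 1L || ncol(X) < 1L) {
    stop("expression matrix must have at least one gene and one cell")
  }
  if (anyNA(X)) stop("expression matrix contains missing values")
  if (min(X) < 0) stop("expression matrix contains negative entries")
  if (anyDuplicated(rownames(X))) {
    dup <- unique(rownames(X)[duplicated(rownames(X))])
    stop("duplicate gene identifiers: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (anyDuplicated(colnames(X))) {
    dup <- unique(colnames(X)[duplicated(colnames(X))])
    stop("duplicate cell identifiers: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (is.null(attr(X, "normalized"))) attr(X, "normalized") <- FALSE
  X
}

is_normalized <- function(X) isTRUE(attr(X, "normalized"))

#' Read an expression matrix from disk
#'
#' Supports two on-disk layouts:
#' \describe{
#'   \item{`dense`}{TSV/CSV with a header row of cell identifiers and a
#'     first column of gene identifiers. Orientation defaults to genes as
#'     rows; set `genes_as = "cols"` for transposed files.}
#'   \item{`mtx`}{MatrixMarket coordinate file plus sidecar
#'     newline-delimited identifier files (`<stem>.genes.txt`,
#'     `<stem>.cells.txt`, or explicit paths). Indices are 1-based per the
#'     MTX standard; rows are genes.}
#' }
#' The returned matrix always has genes as rows and cells as columns.
#'
#' @param path file path (the `.mtx` file for sparse input).
#' @param format `"auto"` (by extension), `"dense"`, or `"mtx"`.
#' @param genes_as for dense files, whether genes are `"rows"` (default) or
#'   `"cols"` on disk.
#' @param gene_file,cell_file optional explicit sidecar paths for `mtx`.
#' @return an [expression_matrix()] (raw; `normalized = FALSE`).
#' @export
read_expression <- function(path, format = c("auto", "dense", "mtx"),
                            genes_as = c("rows", "cols"),
                            gene_file = NULL, cell_file = NULL) {
  format <- match.arg(format)
  genes_as <- match.arg(genes_as)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    if (is.null(gene_file)) gene_file <- paste0(stem, ".genes.txt")
    if (is.null(cell_file)) cell_file <- paste0(stem, ".cells.txt")
    if (!file.exists(gene_file)) stop("gene name file not found: ", gene_file)
    if (!file.exists(cell_file)) stop("cell name file not found: ", cell_file)
    M <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    if (length(genes) != nrow(M)) {
      stop("gene name file has ", length(genes), " entries but matrix has ",
           nrow(M), " rows")
    }
    if (length(cells) != ncol(M)) {
      stop("cell name file has ", length(cells), " entries but matrix has ",
           ncol(M), " columns")
    }
    return(expression_matrix(M, genes, cells))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("malformed dense file (need id column + data): ", path)
  ids <- as.character(tab[[1L]])
  M <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(M)) stop("non-numeric entries in dense expression file: ", path)
  rownames(M) <- ids
  if (genes_as == "cols") M <- t(M)
  expression_matrix(M, rownames(M), colnames(M))
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]; genes are written as rows in both
#' formats. For `mtx`, sidecar `<stem>.genes.txt` / `<stem>.cells.txt`
#' files are written next to the matrix.
#'
#' @param X expression matrix.
#' @param path output path (`.mtx` or dense TSV/CSV).
#' @param format `"auto"`, `"dense"`, or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path, format = c("auto", "dense", "mtx")) {
  format <- match.arg(format)
  X <- validate_expression(X)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    Matrix::writeMM(Matrix::Matrix(unclass(X)[, , drop = FALSE], sparse = TRUE), path)
    writeLines(rownames(X), paste0(stem, ".genes.txt"))
    writeLines(colnames(X), paste0(stem, ".cells.txt"))
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- data.frame(gene_id = rownames(X), X, check.names = FALSE)
    utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read per-cell labels
#'
#' Accepts a two-column TSV (`cell_id<TAB>label`, optional header) or a
#' one-column file of labels in matrix column order. Labels are aligned to
#' `cell_ids` and returned as a named factor; any mismatch between the
#' label file's cells and the matrix's cells is an error that names the
#' offending cells.
#'
#' @param path label file.
#' @param cell_ids cell identifiers of the paired expression matrix.
#' @param min_types minimum number of distinct labels (2 for training).
#' @return factor of length `length(cell_ids)`, names = `cell_ids`.
#' @export
read_labels <- function(path, cell_ids, min_types = 2L) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) >= 2L) {
    # tolerate a header line
    if (identical(tolower(tab[[1L]][1L]), "cell_id")) tab <- tab[-1L, , drop = FALSE]
    ids <- tab[[1L]]
    labs <- tab[[2L]]
    missing_in_file <- setdiff(cell_ids, ids)
    if (length(missing_in_file)) {
      stop("cells absent from label file: ",
           paste(utils::head(missing_in_file, 5L), collapse = ", "))
    }
    extra <- setdiff(ids, cell_ids)
    if (length(extra)) {
      stop("labelled cells absent from matrix: ",
           paste(utils::head(extra, 5L), collapse = ", "))
    }
    labs <- labs[match(cell_ids, ids)]
  } else {
    labs <- tab[[1L]]
    if (length(labs) != length(cell_ids)) {
      stop("one-column label file has ", length(labs),
           " entries for ", length(cell_ids), " cells")
    }
  }
  y <- factor(labs)
  if (nlevels(y) < min_types) {
    stop("need at least ", min_types, " distinct cell types, found ", nlevels(y))
  }
  names(y) <- cell_ids
  y
}

#' Write predicted labels
#'
#' @param labels factor or character vector named by cell id (or paired
#'   with `cell_ids`).
#' @param path output TSV path; columns `cell_id`, `predicted_label`.
#' @param cell_ids optional explicit cell ids.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, cell_ids = names(labels)) {
  if (is.null(cell_ids)) stop("labels must be named by cell id")
  tab <- data.frame(cell_id = cell_ids, predicted_label = as.character(labels))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Library-size normalization
#'
#' `lognorm` scales each cell to a fixed library size (default 10,000
#' counts) and applies `log(1 + x)`; a purely per-column operation, so the
#' gene set and zero pattern are unchanged. `none` returns the input with
#' the normalized flag set (for data normalized upstream).
#'
#' @param X raw expression matrix.
#' @param method `"lognorm"` or `"none"`.
#' @param scale_factor target library size for `lognorm`.
#' @return normalized expression matrix.
#' @export
normalize_expression <- function(X, method = c("lognorm", "none"),
                                 scale_factor = 1e4) {
  method <- match.arg(method)
  X <- validate_expression(X)
  if (method == "none") {
    attr(X, "normalized") <- TRUE
    return(X)
  }
  lib <- colSums(X)
  if (any(lib == 0)) {
    bad <- colnames(X)[lib == 0]
    stop("cells with zero library size: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  out <- log1p(sweep(unclass(X), 2L, lib / scale_factor, "/"))
  expression_matrix(out, rownames(X), colnames(X), normalized = TRUE)
}

#' Restrict two matrices to their shared genes
#'
#' Both outputs are subset to the intersection of their gene sets, rows
#' sorted lexicographically so the two matrices have identical row order.
#'
#' @param train,test expression matrices.
#' @return list with elements `train` and `test`.
#' @export
intersect_genes <- function(train, test) {
  train <- validate_expression(train)
  test <- validate_expression(test)
  shared <- sort(intersect(rownames(train), rownames(test)), method = "radix")
  if (length(shared) == 0L) stop("train and test share no genes")
  list(
    train = expression_matrix(unclass(train)[shared, , drop = FALSE],
                              normalized = is_normalized(train)),
    test = expression_matrix(unclass(test)[shared, , drop = FALSE],
                             normalized = is_normalized(test))
  )
}
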