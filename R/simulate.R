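#' Simulation configuration
#'
#' Describes a labelled scRNA-seq-like dataset with controllable
#' correlation structure between cell types. Types sharing a
#' `base_profile_group` get the same underlying mean profile up to a small
#' multiplicative perturbation, making their mean profiles highly
#' correlated; types in distinct groups draw independent profiles and are
#' lowly correlated. Each type additionally gets a disjoint set of
#' exclusive marker genes: a marker's expected count is `marker_fold`
#' times the typical baseline abundance (`exp(mean_log)`) in its own type
#' and exactly zero in every other type, so markers are type-exclusive
#' without dominating the profile. Counts are negative binomial around
#' the type means with independent Bernoulli dropout.
#'
#' @param n_genes number of genes.
#' @param types data.frame with columns `name`, `n_cells`,
#'   `group` (base profile group id); or a list coercible to one.
#' @param within_group_perturbation sd of the per-gene log-normal
#'   perturbation separating types within a group (default 0.02).
#' @param n_markers_per_type exclusive markers planted per type.
#' @param marker_fold marker expected count in its own type, in units of
#'   the typical baseline abundance `exp(mean_log)`.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param dropout_rate probability an observed count is zeroed.
#' @param mean_log,sd_log log-normal parameters of the baseline gene
#'   means.
#' @param seed integer seed; everything is drawn from it.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000L,
                       types = data.frame(
                         name = paste0("type", 1:4),
                         n_cells = 500L,
                         group = paste0("g", 1:4)),
                       within_group_perturbation = 0.02,
                       n_markers_per_type = 12L,
                       marker_fold = 5,
                       nb_dispersion = 0.5,
                       dropout_rate = 0.3,
                       mean_log = -0.5, sd_log = 2,
                       seed = 1L) {
  types <- as.data.frame(types)
  stopifnot(all(c("name", "n_cells", "group") %in% names(types)),
            n_genes >= 1L, n_markers_per_type >= 0L, marker_fold > 0,
            nb_dispersion > 0, dropout_rate >= 0, dropout_rate < 1,
            all(types$n_cells >= 1L))
  if (anyDuplicated(types$name)) stop("duplicate type names")
  if (n_markers_per_type * nrow(types) > n_genes) {
    stop("marker genes (", n_markers_per_type * nrow(types),
         ") exceed n_genes (", n_genes, ")")
  }
  structure(list(n_genes = as.integer(n_genes), types = types,
                 within_group_perturbation = within_group_perturbation,
                 n_markers_per_type = as.integer(n_markers_per_type),
                 marker_fold = marker_fold, nb_dispersion = nb_dispersion,
                 dropout_rate = dropout_rate,
                 mean_log = mean_log, sd_log = sd_log,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a labelled count matrix
#'
#' Fully seeded: identical configurations give identical output. The
#' dropout mask compares a uniform draw against `dropout_rate`, so for a
#' fixed seed a higher rate zeroes a superset of the entries a lower rate
#' zeroes.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (raw [expression_matrix()]), `labels`
#'   (factor named by cell), `markers` (per-type planted marker gene ids),
#'   and `type_means` (genes x types expected-count matrix).
#' @export
simulate_cells <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes
  K <- nrow(cfg$types)
  gene_ids <- sprintf("g%05d", seq_len(G))
  groups <- unique(cfg$types$group)
  base <- vapply(groups, function(g) {
    stats::rlnorm(G, meanlog = cfg$mean_log, sdlog = cfg$sd_log)
  }, numeric(G))
  colnames(base) <- groups

  marker_ids <- list()
  marker_pool <- sample.int(G, cfg$n_markers_per_type * K)
  mu <- matrix(0, G, K, dimnames = list(gene_ids, cfg$types$name))
  for (k in seq_len(K)) {
    b <- base[, cfg$types$group[k]]
    mu[, k] <- b * exp(stats::rnorm(G, 0, cfg$within_group_perturbation))
    idx <- if (cfg$n_markers_per_type > 0L) {
      marker_pool[((k - 1L) * cfg$n_markers_per_type + 1L):
                    (k * cfg$n_markers_per_type)]
    } else integer(0)
    marker_ids[[cfg$types$name[k]]] <- gene_ids[idx]
  }
  # markers: moderate fixed abundance in their own type, silent elsewhere
  for (k in seq_len(K)) {
    idx <- match(marker_ids[[cfg$types$name[k]]], gene_ids)
    if (length(idx)) {
      mu[idx, ] <- 0
      mu[idx, k] <- cfg$marker_fold * exp(cfg$mean_log)
    }
  }

  n_total <- sum(cfg$types$n_cells)
  counts <- matrix(0, G, n_total)
  labels <- character(n_total)
  cell_ids <- character(n_total)
  pos <- 0L
  for (k in seq_len(K)) {
    nk <- cfg$types$n_cells[k]
    cols <- pos + seq_len(nk)
    counts[, cols] <- stats::rnbinom(G * nk, mu = mu[, k],
                                     size = 1 / cfg$nb_dispersion)
    labels[cols] <- cfg$types$name[k]
    cell_ids[cols] <- sprintf("%s_c%04d", cfg$types$name[k], seq_len(nk))
    pos <- pos + nk
  }
  # dropout mask drawn unconditionally so the stream is rate-independent
  u <- matrix(stats::runif(G * n_total), G, n_total)
  counts[u < cfg$dropout_rate] <- 0
  # a fully zero cell cannot be library-size normalized; give it one count
  dead <- colSums(counts) == 0
  if (any(dead)) counts[1L, dead] <- 1
  X <- expression_matrix(counts, gene_ids, cell_ids)
  y <- factor(labels, levels = cfg$types$name)
  names(y) <- cell_ids
  list(counts = X, labels = y, markers = marker_ids, type_means = mu)
}

#' Stratified train/test split
#'
#' Draws `train_fraction` of each type's cells as the training set, then
#' `test_size` cells from the remainder (allocated across types
#' proportionally to what remains). Train and test are disjoint; the
#' split is seeded.
#'
#' @param X expression matrix.
#' @param y labels aligned to `X`.
#' @param train_fraction proportion of each type used for training.
#' @param test_size total number of test cells; `NULL` takes all
#'   remaining cells.
#' @param seed integer seed.
#' @return list with `train = list(X, y)` and `test = list(X, y)`.
#' @export
split_cells <- function(X, y, train_fraction = 0.5, test_size = NULL,
                        seed = 1L) {
  X <- validate_expression(X)
  y <- align_labels(y, X)
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(as.integer(seed))
  idx_by_type <- split(seq_len(ncol(X)), y)
  train_idx <- unlist(lapply(idx_by_type, function(ix) {
    sample(ix, max(1L, round(train_fraction * length(ix))))
  }), use.names = FALSE)
  rest <- setdiff(seq_len(ncol(X)), train_idx)
  if (is.null(test_size)) {
    test_idx <- rest
  } else {
    if (test_size > length(rest)) {
      stop("test_size (", test_size, ") exceeds the ", length(rest),
           " cells left after the training draw")
    }
    # proportional allocation per type, largest remainders absorb rounding
    rest_by_type <- split(rest, y[rest])
    quota <- test_size * lengths(rest_by_type) / length(rest)
    take <- floor(quota)
    short <- test_size - sum(take)
    if (short > 0L) {
      bump <- order(quota - take, decreasing = TRUE)[seq_len(short)]
      take[bump] <- take[bump] + 1L
    }
    test_idx <- unlist(mapply(function(ix, m) {
      if (m > length(ix)) m <- length(ix)
      sample(ix, m)
    }, rest_by_type, take, SIMPLIFY = FALSE), use.names = FALSE)
  }
  subset_pair <- function(ix) {
    list(X = expression_matrix(unclass(X)[, ix, drop = FALSE],
                               normalized = is_normalized(X)),
         y = droplevels(y[ix]))
  }
  list(train = subset_pair(sort(train_idx)), test = subset_pair(sort(test_idx)))
}
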