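# Small in-code fixtures shared across test files.

# a tiny deterministic raw count matrix
tiny_counts <- function() {
  expression_matrix(
    matrix(c(10, 0, 5,
             0, 2, 3), nrow = 3,
           dimnames = list(c("gA", "gB", "gC"), c("cell1", "cell2"))))
}

# quick simulated dataset; grouped = TRUE makes types 1 and 2 highly
# correlated (shared base profile, 2% perturbation)
quick_sim <- function(seed, grouped = FALSE, n_genes = 2000L,
                      cells_per_type = 100L, dropout = 0.3) {
  grp <- if (grouped) c("g1", "g1", "g2", "g3") else paste0("g", 1:4)
  cfg <- sim_config(
    n_genes = n_genes,
    types = data.frame(name = paste0("type", 1:4),
                       n_cells = cells_per_type, group = grp),
    dropout_rate = dropout, seed = seed)
  simulate_cells(cfg)
}

# two well-separated 2-feature blobs, as a normalized expression matrix
blob_data <- function(n_per_class = 40L, seed = 7L, sep = 10) {
  set.seed(seed)
  n <- 2L * n_per_class
  vals <- rbind(
    abs(c(stats::rnorm(n_per_class, 1, 0.5), stats::rnorm(n_per_class, 1 + sep, 0.5))),
    abs(c(stats::rnorm(n_per_class, 1 + sep, 0.5), stats::rnorm(n_per_class, 1, 0.5))))
  X <- expression_matrix(vals, c("gx", "gy"), sprintf("c%03d", seq_len(n)),
                         normalized = TRUE)
  y <- factor(rep(c("alpha", "beta"), each = n_per_class))
  names(y) <- colnames(X)
  list(X = X, y = y)
}
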