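test_that("lineage tree topology matches agglomerative structure", {
  # K = 2: the only possible topology is a single root bifurcation
  A2 <- cbind(a = c(1, 0, 2), b = c(0, 1, 5))
  rownames(A2) <- paste0("g", 1:3)
  t2 <- build_lineage_tree(A2)
  expect_identical(sort(t2$root$types), c("a", "b"))
  expect_identical(count_internal <- scLineageNet:::count_internal_nodes(t2$root), 1L)

  # two tight pairs merge before the pairs join each other
  A4 <- cbind(p1a = c(0, 0), p1b = c(0.1, 0), p2a = c(10, 10), p2b = c(10, 10.1))
  rownames(A4) <- c("g1", "g2")
  t4 <- build_lineage_tree(A4)
  sets <- tree_node_sets(t4$root)
  expect_true(any(vapply(sets, identical, TRUE, y = c("p1a", "p1b"))))
  expect_true(any(vapply(sets, identical, TRUE, y = c("p2a", "p2b"))))

  # K = 8 random profiles: K leaves and K-1 internal nodes
  set.seed(8)
  A8 <- matrix(stats::rlnorm(80), 10, 8,
               dimnames = list(paste0("g", 1:10), paste0("k", 1:8)))
  t8 <- build_lineage_tree(A8)
  expect_length(t8$types, 8L)
  expect_identical(scLineageNet:::count_internal_nodes(t8$root), 7L)
  expect_error(build_lineage_tree(A8[, 1, drop = FALSE]), "at least 2")
  # newick export mentions every type
  nwk <- export_tree_newick(t8)
  expect_true(all(vapply(paste0("k", 1:8), grepl, TRUE, x = nwk)))
})

test_that("complete linkage matches the brute-force oracle on random instances", {
  set.seed(99)
  for (K in 2:6) {
    A <- matrix(stats::rlnorm(12 * K), 12, K,
                dimnames = list(paste0("g", 1:12), paste0("k", 1:K)))
    tree <- build_lineage_tree(A)
    oracle <- oracle_complete_linkage(A)
    expect_equal(sort(tree$hclust$height), sort(oracle$heights),
                 tolerance = 1e-12)
    got_sets <- tree_node_sets(tree$root)
    expect_setequal(vapply(got_sets, paste, "", collapse = "|"),
                    vapply(oracle$sets, paste, "", collapse = "|"))
  }
})

test_that("marker sensitivity counts expressing cells per type", {
  X <- expression_matrix(matrix(c(
    1, 1, 1, 0,   # gk: only in type k cells (cells 1-3 are k)
    0, 0, 0, 0,   # gnone: expressed nowhere
    2, 5, 1, 3),  # gmix: 3 k cells + 1 j cell
    nrow = 3, byrow = TRUE,
    dimnames = list(c("gk", "gnone", "gmix"), paste0("c", 1:4))))
  y <- factor(c("k", "k", "k", "j"))
  sens <- marker_sensitivity(X, y, nu1 = 0)
  expect_equal(sens$Sen["gk", "k"], 1)
  expect_equal(sens$Sen["gk", "j"], 0)
  expect_equal(sens$Sen["gnone", ], c(j = 0, k = 0))
  expect_equal(sens$Sen["gmix", "k"], 0.75)
  expect_equal(sens$Sen, oracle_sensitivity(unclass(X), y), tolerance = 1e-15)
  # expressed genes have sensitivities summing exactly to 1
  expressed <- rowSums(unclass(X) > 0) > 0
  expect_equal(rowSums(sens$Sen[expressed, ]), c(gk = 1, gmix = 1))
})

test_that("sensitivity matches the counting oracle on random matrices", {
  set.seed(15)
  for (rep in 1:5) {
    X <- expression_matrix(
      matrix(stats::rbinom(20 * 12, 3, 0.3), 20, 12,
             dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:12))))
    y <- factor(sample(c("a", "b", "c"), 12, replace = TRUE,
                       prob = c(0.4, 0.4, 0.2)))
    if (nlevels(droplevels(y)) < 2) next
    sens <- marker_sensitivity(X, droplevels(y), nu1 = 0)
    expect_equal(sens$Sen, oracle_sensitivity(unclass(X), droplevels(y)),
                 tolerance = 1e-12)
    expressed <- rowSums(unclass(X) > 0) > 0
    if (any(expressed)) {
      expect_equal(unname(rowSums(sens$Sen[expressed, , drop = FALSE])),
                   rep(1, sum(expressed)))
    }
  }
})

test_that("marker pre-assignment enforces strict thresholds and uniqueness", {
  # type A eligible with 11 markers, type B not eligible (only 2 markers)
  genesA <- paste0("mA", 1:11)
  genesB <- paste0("mB", 1:2)
  sens <- structure(list(
    Sen = NULL,
    marker_sets = list(A = genesA, B = genesB),
    eligible_types = "A", sen_threshold = 0.95, nu1 = 10L),
    class = "sensitivity_table")
  mk_cell <- function(n_expressed_A) {
    v <- numeric(13)
    v[seq_len(n_expressed_A)] <- 1
    v
  }
  X1 <- expression_matrix(
    cbind(c4 = mk_cell(4), c3 = mk_cell(3), c11 = mk_cell(11), c0 = mk_cell(0)),
    gene_ids = c(genesA, genesB))
  out <- marker_preassign(X1, sens, nu2 = 3)
  expect_identical(out[["c4"]], "A")    # 4 > nu2 = 3
  expect_true(is.na(out[["c3"]]))       # exactly 3 is deferred (strict >)
  expect_identical(out[["c11"]], "A")
  expect_true(is.na(out[["c0"]]))
  # a cell exceeding nu2 for two eligible types is deferred
  sens2 <- sens
  sens2$eligible_types <- c("A", "B")
  sens2$marker_sets$B <- paste0("mB", 1:11)
  X2 <- expression_matrix(
    matrix(1, 22, 1, dimnames = list(c(genesA, paste0("mB", 1:11)), "amb")))
  expect_true(is.na(marker_preassign(X2, sens2, nu2 = 3)[["amb"]]))
  expect_error(marker_preassign(X1, sens, nu2 = -1), "nu2")
})

test_that("bifurcation features recover planted differential genes", {
  set.seed(31)
  G <- 2000L; n <- 60L
  planted <- sprintf("g%04d", sample(G, 50))
  ids <- sprintf("g%04d", 1:G)
  X <- matrix(abs(stats::rnorm(G * n, 2, 1)), G, n,
              dimnames = list(ids, sprintf("c%03d", 1:n)))
  y <- factor(rep(c("L", "R"), each = n / 2))
  X[planted, y == "R"] <- X[planted, y == "R"] + 5  # 5-sigma shift
  Xe <- expression_matrix(X, normalized = TRUE)
  top <- bifurcation_features(Xe, y, "L", "R", M = 1000)
  expect_length(top, 1000L)
  expect_true(all(planted %in% top))
  # concordant with an independent Welch-t ranking for the strong genes
  wt <- abs(oracle_welch_t(X, y == "R"))
  oracle_top <- names(sort(wt, decreasing = TRUE))[1:50]
  expect_true(all(oracle_top %in% top))
  # G < M returns every gene
  small <- expression_matrix(X[1:200, ], normalized = TRUE)
  expect_length(bifurcation_features(small, y, "L", "R", M = 1000), 200L)
  # determinism under identical inputs
  expect_identical(top, bifurcation_features(Xe, y, "L", "R", M = 1000))
  # single-cell branch falls back with a warning
  ysmall <- factor(c("L", rep("R", n - 1)), levels = c("L", "R"))
  expect_warning(bifurcation_features(Xe, ysmall, "L", "R", M = 10),
                 "mean difference")
})

test_that("hierarchy training fits one binary network per bifurcation", {
  sim <- quick_sim(seed = 61, grouped = TRUE, n_genes = 600,
                   cells_per_type = 60)
  X <- normalize_expression(sim$counts)
  A <- mean_profiles(X, sim$labels)
  tree <- build_lineage_tree(A)
  h <- train_hierarchy(X, sim$labels, tree, config = train_config(
    epochs = 8, seed = 3), M = 200)
  n_clf <- 0L
  walk <- function(node) {
    if (isTRUE(node$leaf)) return(invisible(NULL))
    expect_s3_class(node$clf, "ff_classifier")
    expect_true(node$clf$trained)
    expect_identical(node$clf$gene_order, node$features)
    expect_true(length(node$features) > 0)
    n_clf <<- n_clf + 1L
    walk(node$left); walk(node$right)
  }
  walk(h$tree$root)
  expect_identical(n_clf, 3L)   # K - 1 bifurcations for K = 4

  # prediction is exhaustive and marker pre-assignments are never overridden
  pred <- predict_hierarchical(h, X, nu2 = 3)
  expect_false(anyNA(pred$labels))
  expect_true(all(pred$labels %in% levels(sim$labels)))
  pre <- marker_preassign(X, h$sensitivity, nu2 = 3)
  assigned <- !is.na(pre)
  expect_identical(as.character(pred$labels[assigned]), unname(pre[assigned]))
  expect_identical(pred$n_preassigned, sum(assigned))
})

test_that("a perfectly separable two-type hierarchy classifies its training set", {
  d <- blob_data(n_per_class = 30, seed = 23)
  A <- mean_profiles(d$X, d$y)
  tree <- build_lineage_tree(A)
  h <- train_hierarchy(d$X, d$y, tree, config = train_config(
    epochs = 30, seed = 2), M = 2, nu1 = 10)
  pred <- predict_hierarchical(h, d$X)
  expect_equal(annotation_accuracy(pred$labels, d$y), 1.0)
})

test_that("a node probability of exactly 0.5 routes to the right branch", {
  d <- blob_data(n_per_class = 10, seed = 2)
  fit <- train_network(build_network(2, 2, network_spec("small"), seed = 1,
                                     output = "sigmoid"),
                       d$X, factor(d$y, labels = c("left", "right")),
                       train_config(epochs = 2, seed = 1))
  for (l in seq_along(fit$W)) { fit$W[[l]][] <- 0; fit$b[[l]][] <- 0 }
  pred <- predict_network(fit, d$X)   # all probabilities exactly 0.5
  expect_true(all(as.numeric(pred$probs) == 0.5))
  expect_true(all(pred$labels == "right"))
})
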