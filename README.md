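# scLineageNet

Supervised cell-type annotation for single-cell RNA-seq. Given a reference
expression matrix with known cell-type labels and an unlabelled query
matrix, `scLineageNet` assigns every query cell a concrete label from the
reference — no "unassigned" outcomes — choosing its classifier from the
correlation structure of the reference itself.

## The method

Cell types such as the T-cell subsets of PBMC data can have mean expression
profiles with Pearson correlation above 0.95; flat multi-class classifiers
and correlation-based mappers struggle exactly there. `scLineageNet`
computes the genes × types profile matrix **A** (per-type mean expression),
its K × K Pearson correlation matrix **P**, and dispatches on the largest
off-diagonal entry against a threshold τ (default 0.95):

* **Flat mode** (`max p_ij < τ`): a single feed-forward neural network —
  ReLU hidden layers of width 64 / 64,128 / 64,128,256 for the small /
  medium / big model sizes, softmax output
  `p_ik = exp(η_ik) / Σ_j exp(η_ij)` — trained with mini-batch RMSprop on
  the categorical cross-entropy `L(Θ) = −(1/n) Σ_i 1(y_i = k) log p̂_ik`.
* **Hierarchical mode** (`max p_ij ≥ τ`): a cell-lineage tree from
  complete-linkage clustering of the columns of **A**. Cells are first
  pre-assigned by highly sensitive markers: for gene g and type k,
  `Sen_gk = #(cells expressing g of type k) / #(cells expressing g)`; genes
  with `Sen_gk > 0.95` are type-specific, types with more than ν₁ = 10 such
  markers are eligible, and a query cell expressing more than ν₂ = 3
  markers of exactly one eligible type takes that label. Remaining cells
  descend the tree: each bifurcation carries its own top-M = 1000 features
  (limma moderated-t ranking, left vs right branch) and a binary network
  trained with binary cross-entropy; a cell goes right when p̂ ≥ 0.5 and
  receives the label of the leaf it reaches.

Predictions are scored by the accurately assigned rate (exact-match
fraction) and the adjusted Rand index.

The package also ships a seeded negative-binomial simulator
(`simulate_cells()`) whose type groups reproduce the two regimes —
highly correlated pairs (profile r ≥ 0.95) and well-separated types — with
planted exclusive markers and dropout, so the whole pipeline is testable
without external data.

## Worked example

```r
library(scLineageNet)

cfg <- sim_config(types = data.frame(name = c("naiveT", "memoryT", "NK", "mono"),
                                     n_cells = 300,
                                     group = c("lymphoid", "lymphoid", "nk", "myeloid")),
                  seed = 101)
sim <- simulate_cells(cfg)                # raw counts + true labels
sp  <- split_cells(sim$counts, sim$labels, train_fraction = 0.5, seed = 1)
res <- annotate_cells(sp$train$X, sp$train$y, sp$test$X,
                      config = train_config(seed = 1))
print(res$annotator)
print(evaluate_annotation(res$labels, sp$test$y))
```

```
cell annotator: hierarchical mode, 4 types, 2000 genes
strategy: hierarchical (max off-diagonal profile correlation 0.9764 >= tau = 0.95)
most correlated pair: memoryT / naiveT
n = 600 cells | accurately assigned rate = 0.9967 | ARI = 0.9911
         pred
truth     memoryT mono naiveT  NK
  memoryT     149    0      1   0
  mono          0  150      0   0
  naiveT        1    0    149   0
  NK            0    0      0 150
```

The two lymphoid types share a base profile (r = 0.98 ≥ τ), so the
hierarchical route is chosen; it separates them almost perfectly while the
distinct NK and monocyte types are trivially recovered. With four
independent groups instead, the same call selects flat mode.

A shell interface with `simulate`, `annotate`, `train`, `predict` and
`evaluate` subcommands is installed under `exec/sclineagenet`
(`--tau`, `--model-size`, `--nu1`, `--nu2`, `--n-features`, `--seed`, ...).

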