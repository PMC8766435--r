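---
title: "Correlation-guided neural annotation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-guided neural annotation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scLineageNet)
```

## The annotation problem

Supervised cell-type annotation transfers labels from a reference
scRNA-seq dataset with known identities (e.g. FACS-sorted populations) to
an unlabelled query. The failure mode that motivates this package is
*highly correlated cell types*: populations like naive, helper and
regulatory T cells whose mean expression profiles correlate above 0.95.
A single multi-class classifier spreads its capacity across all types at
once and has no mechanism to focus on the few genes that separate a
difficult pair; correlation-based mappers tend to return "unassigned" for
exactly those cells. The design principle here is to *measure* how hard
the reference is and to spend model capacity accordingly — and to always
return a concrete label for every cell.

## Dispatch rule

Training starts from the genes × K profile matrix `A` of per-type mean
expression and its K × K Pearson correlation matrix `P` (both on
library-size-normalized, log1p-transformed values). If every off-diagonal
`p_ij` is below the threshold `tau`, a single feed-forward network is
trained; otherwise the hierarchical route is taken. The comparison is
inclusive (`p_ij >= tau` engages the hierarchy), and `tau = 0.95` by
default. `tau` is exposed (`--tau`, argument `tau`) rather than
auto-tuned: no selection rule is obviously right, smaller values simply
encourage the hierarchical route for complicated references, and forcing
either mode is available for diagnosis (`force_mode`).

A profile column with zero variance makes the Pearson coefficient
undefined; we treat it as an error naming the type rather than skipping
it, since a classifier trained against a constant profile is meaningless.

## The dense network

All classifiers share one architecture family: fully connected ReLU
layers with hidden widths 64 (small), 64,128 (medium) or 64,128,256
(big), then a softmax head over the K types (flat mode) or a single
sigmoid unit (tree nodes). Note the stock sizes are specified by their
width lists; we count one, two and three hidden layers respectively,
treating the input and output layers as the remainder of the stack.

Training minimizes categorical cross-entropy (softmax) or binary
cross-entropy (sigmoid) by mini-batch RMSprop. Hyperparameters and their
defaults, all exposed through `train_config()`:

| parameter | default | notes |
|---|---|---|
| `batch_size` | 128 cells | mini-batch sampling reshuffled each epoch |
| `epochs` | 30 | fixed budget; no early stopping |
| `learning_rate` | 1e-3 | RMSprop step size |
| `rho` | 0.9 | squared-gradient decay |
| `epsilon` | 1e-7 | denominator stabilizer |
| `validation_fraction` | 0 | optional held-out loss trace |

These are the framework-standard RMSprop settings; the architecture
widths, `tau`, and the marker parameters below are the method-level
choices, and the optimizer settings rarely need touching. Batch
normalization and dropout layers are deliberately absent — on this model
family they do not change performance appreciably, and omitting them
keeps training exactly reproducible from one seed.

Numerical details worth stating: softmax is computed with
max-subtraction; probabilities entering any logarithm are clamped to
`[1e-12, 1 - 1e-12]`, so a confident wrong prediction yields a large
finite loss, never `-Inf`; weights are initialized uniform Glorot-style
from the seed, and batch order is drawn from the same seed, so identical
configurations give bitwise-identical models; argmax ties at prediction
go to the lowest class index, and a node probability of exactly 0.5
routes to the right branch — both arbitrary but documented and
deterministic. Training genes missing from a query matrix are imputed as
zero rows with a warning (after `intersect_genes()` this only happens
when a saved model meets new data); a query sharing no genes at all with
the model is an error.

## The hierarchical route

1. **Lineage tree.** Complete-linkage agglomerative clustering of the
   profile columns, Euclidean distance. The linkage is the method's
   choice; the metric is ours — Euclidean on normalized profiles is the
   common default and keeps the tree consistent with the profile space
   the dispatch rule already uses. `hclust`'s deterministic merge order
   (ties resolved by column order) is relied upon, and the same
   brute-force O(K³) agglomeration is used as a test oracle.
2. **Marker pre-assignment.** `Sen_gk` is the fraction of cells
   expressing gene g that belong to type k — implemented as a ratio of
   counts over cells, the only reading that yields a [0,1] sensitivity
   summing to 1 across types for every expressed gene. Genes with
   `Sen_gk > 0.95` are type-specific; types with strictly more than
   `nu1 = 10` of them are eligible; a query cell expressing strictly more
   than `nu2 = 3` markers of exactly one eligible type is labelled
   immediately and never revisited. Both inequalities are strict, and a
   cell exceeding `nu2` for two types is deferred to the tree rather than
   arbitrarily resolved. Expression means "value > 0", which log1p
   library scaling preserves, so markers behave identically on raw and
   normalized input.
3. **Per-bifurcation features.** Each internal node ranks genes by the
   absolute moderated t-statistic (limma's empirical-Bayes shrunken
   variances) contrasting pooled left-branch against pooled right-branch
   training cells, and keeps the top `M = 1000` (ties broken by gene id;
   constant genes score 0 without entering the fit). A branch with fewer
   than two cells falls back to mean-difference ranking with a warning.
   Only the ranking is consumed — no p-values are interpreted.
4. **Node networks.** Each bifurcation trains its own binary network on
   its feature subset, using only cells whose type belongs to the node's
   leaf set, with target 1 for the right branch. Node networks reuse the
   user-selected model size: nothing suggests bifurcations need a
   different capacity, and one knob is easier to reason about. Each node
   derives its own seed from the global one, so nodes are independently
   reproducible.
5. **Traversal.** Deferred cells descend root → leaf (right when
   p̂ ≥ 0.5) and take the leaf's label. Together with pre-assignment this
   makes annotation exhaustive: every cell ends at a leaf, and only
   training-set labels exist at leaves.

## Normalization

Library-size scaling to 10,000 counts per cell followed by `log(1 + x)`,
the de-facto standard of this ecosystem, applied once upstream of
everything — profiles, correlation, feature selection and network
training all see the same values (only marker logic reduces to
positivity, where normalization is irrelevant). `method = "none"` passes
pre-normalized data through. A cell with zero library size is a hard
error, not a silent drop, so count bookkeeping stays honest.

## What the simulator emulates

`simulate_cells()` generates the two regimes the method distinguishes:

* **Baseline profiles** per group: log-normal gene means
  (`mean_log = -0.5`, `sd_log = 2`). The wide spread matters — real
  log-normalized profiles span silent to abundant genes, and that shared
  dynamic range is what keeps two closely related types correlated above
  0.95 despite their distinguishing genes.
* **Grouped types** share a base profile up to a per-gene multiplicative
  perturbation (`within_group_perturbation = 0.02`), giving empirical
  profile correlations ≈ 0.97–0.99; distinct groups draw independent
  profiles and land near 0.
* **Markers**: disjoint per-type gene sets (12 by default), expected
  count `marker_fold × exp(mean_log)` (≈ 3) in their own type and exactly
  zero elsewhere. Moderate abundance is a deliberate compromise: strong
  enough that a cell typically expresses well over `nu2` of them, weak
  enough that exclusive zeros do not drag grouped-type correlations below
  the dispatch threshold.
* **Counts**: negative binomial with dispersion 0.5
  (variance `mu + 0.5 mu²`), then independent Bernoulli dropout
  (`dropout_rate = 0.3`); overall sparsity at defaults is ≈ 70%. The
  dropout mask thresholds one uniform draw per entry, so for a fixed seed
  a higher rate zeroes a superset of entries — a property the tests use.

The simulator does **not** model batch effects, doublets, ambient RNA,
gene-length bias or realistic library-size variation, and its types are
exactly the generative groups. Passing tests on it demonstrate that the
pipeline recovers planted structure under count noise and dropout — not
that any particular accuracy transfers to real tissues, where boundaries
between types are biological rather than generative.

## Problem sizes and reproducibility

The shipped tests and `scripts/acceptance.R` run entirely on simulated
data at desk scale, chosen to exercise every code path in a few minutes
on one CPU: 2,000 genes throughout; an easy fixture with four independent
types (500 cells each, half for training, 800 test cells) where flat mode
is selected and accuracy ≥ 0.98; a hard fixture with one grouped pair
(1,000 training cells per type, 800 test cells) where the hierarchy
engages at pair correlation ≈ 0.98 and accuracy ≥ 0.90; 100 dispatch
replicates per regime at 100 cells per type; and a no-dropout,
12-markers-per-type fixture for the `nu1`/`nu2` logic. Every random
choice — simulation, splits, weight initialization, batch order — flows
from explicit integer seeds, and re-running any entry point with the same
configuration reproduces its output byte for byte.

## Known limitations

* Query cells of a type absent from the reference are still assigned the
  nearest reference label — exhaustiveness is a feature for benchmarked
  references and a caveat for discovery settings; there is no novelty
  rejection.
* The moderated-t feature selection assumes roughly log-scale Gaussian
  pseudo-replicates within branches; heavy multimodality within a branch
  (e.g. a badly built tree) degrades the ranking silently.
* Marker pre-assignment keys on positivity alone, so ambient
  contamination that turns exclusive markers weakly positive across types
  would erode both eligibility and pre-assignment precision.
* Training is CPU-bound dense linear algebra; references beyond ~10⁵
  cells × 2·10⁴ genes will want subsampling.
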