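---
title: "Hierarchical graph-transformer embeddings for spatial omics: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical graph-transformer embeddings for spatial omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`spathgt` learns self-supervised embeddings for single-cell spatial
transcriptomics and proteomics by modelling a tissue as a two-level graph:

* **Cell level.** Cells are nodes of a spatial graph; two cells are adjacent
  iff their Voronoi regions share a border (computed as the Delaunay
  triangulation, with edges beyond the 0.99 length quantile pruned to remove
  convex-hull artifacts).
* **Gene level.** Each cell carries a copy of the gene co-expression network
  of its cell type: nodes are genes, and two genes are connected when the
  mutual information of their denoised expression across the cells of that
  type exceeds a threshold.

The encoder stacks `L` layers. Each layer first runs *intra-level* message
passing — neighbour-restricted multi-head attention with pre-norm residual
blocks and a feed-forward network, on the spatial graph for cells and on each
cell's co-expression network for genes (all cells of a type are processed as
a block-diagonal batch over the shared topology) — and then *cross-level*
directional message passing. For aligned row matrices the cross-level update
is

$$\mathrm{CMP}(H_{to}, H_{from}) =
  \frac{\langle H_{to}W_q,\ H_{from}W_k\rangle}{d}\cdot H_{to}W_v,$$

where the inner product is row-wise, so each row receives a *scalar gate*
times its own value vector. Genes receive their parent cell's state repeated
over the cell's gene rows; cells receive the pooled summary of their gene
rows (mean by default; a one-cluster differentiable pooling is available via
`agg = "diffpool"`). The denominator is `d`, not `sqrt(d)` — deliberately,
as that is the published form of the operator; `cross_message_passing()`
exposes it directly and the test suite pins hand-computed cases. Because the
gate can annihilate the state, the cross-level update defaults to a residual
form (`cross_residual = TRUE`); the bare equation is available by switching
that flag.

A consequence worth stating explicitly: per layer, the gene-to-cell channel
has a bandwidth of one scalar per cell. Transcriptional information enters
cell embeddings only through these gates (amplified and spatially mixed by
the next layer's attention), which makes cell-level structure recovery a
genuinely hard, slow-to-train property at desk scale — see "Known
limitations" below.

Initial embeddings are positional encodings, with no learned map before the
additive raw features (passing raw features through an MLP first measurably
hurts reconstruction-style tasks, because it smooths fine-grained local
variation): gene row (k, v) is the base-10000 sinusoidal encoding of the rank
of gene v's denoised expression within cell k (rank 1 = highest, ties broken
by gene index) with the raw value added to coordinate 1; cell row k
concatenates d/2-dimensional sinusoidal encodings of the min-max-normalized
x and y coordinates (scaled by `pe_scale = 128` so the frequency ladder
resolves unit-square distances) with the raw normalized coordinates added to
the first coordinate of each half. Patches of a tissue keep the parent
tissue's normalization bounds, so positional encodings agree across training
batches.

The decoder is a 3-layer graph isomorphism network (GIN) per level: from the
final cell embeddings it predicts the normalized coordinates over the
spatial graph, and from the final gene embeddings the per-cell expression
vectors over the co-expression graphs. A layer norm follows each GIN MLP;
without it the sum aggregation inflates the output scale geometrically with
depth.

# Pretraining objectives

Three losses are combined:

* **Spatially-aware contrastive (InfoNCE).** Positive cell pairs are
  same-type cells within radius `r` (default: twice the median spatial edge
  length); the negative set of cell i contains different-type cells within
  `r`. Three terms operate on cosine similarities at temperature 0.1:
  cell–cell on embedding rows, gene–gene on co-expression-adjacent gene
  pairs across positive cell pairs (negatives: non-adjacent genes in
  negative-set cells), and cell–gene between a cell row and the pooled gene
  row of its positive partner (negatives: pooled gene rows of negative-set
  cells). The published per-pair terms are log-probabilities; they are
  implemented as their negation so minimization pulls positives together.
  Each term is the mean over its sampled units (a unit with no negatives
  contributes 0), and the gene–gene sum over all gene pairs is subsampled
  (64 pairs per cell pair by default) since the full cross-product is
  intractable.
* **Masked auto-encoding.** Bernoulli masks hide cell coordinates (rate 0.1)
  and gene entries (rate 0.3); masked inputs are replaced by zero before
  encoding. The loss is the mean squared error restricted to masked entries:
  the mean squared distance between predicted and true normalized
  coordinates over masked cells, plus the per-cell masked-entry expression
  MSE averaged over all cells. Positions are min-max normalized to the unit
  square so both terms share a scale.
* **Orthogonality.** $\lVert I - \hat Z_c^{\top}\hat Z_c\rVert_F^2 +
  \lVert I - \hat Z_g^{\top}\hat Z_g\rVert_F^2$ with columns scaled to unit
  norm before the Gram product — without that normalization the identity
  target is unattainable and the penalty scale grows with the cell count.

The total is $\sigma(\gamma)\,L_{con} + (1-\sigma(\gamma))\,L_{mae} +
\lambda\,L_{ortho}$ with $\lambda = 10^{-3}$ and the balance scalar
$\gamma$ (init 0) trained by the same optimizer as the weights.

# Training

Batches are spatial: seeded anchor cells grow breadth-first neighbourhoods
truncated at `patch_cells` cells, covering every cell; whole small components
become their own patches. A patch-level split (10%) provides validation.
Optimization is Adam (lr 1e-3 by default, no scheduler) with global
gradient-norm clipping at 5; early stopping monitors the validation loss
under fixed per-patch masks and sampling seeds so epochs are comparable, with
`patience = 0` meaning exactly one epoch. Because the gene-to-cell channel is
a scalar gate, contrastive structure emerges slowly; recipes that aim at
structure recovery (rather than reconstruction) benefit from smaller patches
(more optimizer steps per epoch), the full positive-pair set per patch
(`max_pos_pairs` large, less sampling noise) and lr around 2e-3.

Everything runs on an in-package reverse-mode autodiff tape (`R/ad.R`):
dense matmuls, sparse scatter products, fused edge-list attention, fused
block-diagonal dense attention for the per-cell gene graphs, layer norm, and
the loss ops. Gradients of every op — and of the full model loss — are
verified against central finite differences in the test suite, and the two
attention implementations are cross-checked against each other.

# The synthetic tissue generator

`generate_tissue()` plants exactly the structures the model is built to
exploit, with ground truth retained for recovery tests:

* positions uniform in the unit square; **niches** are Voronoi regions of
  `n_niches` anchors placed by farthest-point sampling (balanced, meso-scale
  regions — with uniformly drawn anchors the regions are often slivers that
  even clean expression plus exact positions cannot recover, which would
  make every structure-recovery benchmark vacuous);
* **cell types** drawn from a niche-dependent mixture (the favoured type has
  probability 0.5, the rest uniform), so niches modulate composition without
  determining type;
* **expression** = softplus(gene baseline + type marker shift (+2 on the
  type's home-module genes) + shared module factors (within-module
  correlation) + `niche_effect` × per-niche offsets on a third of the genes
  + Gaussian noise (`noise_sd = 0.3`));
* **dropout**: i.i.d. Bernoulli zeroing at `dropout_rate`.

Defaults (1500 cells, 60 genes, 3 types, 3 niches, 2 modules per type,
dropout 0.4, niche effect 0.8) are calibrated so that spectral clustering of
*clean* expression recovers the type labels with NMI ≥ 0.9 — the declared
difficulty of the benchmark suite — while the *observed* (dropout-corrupted)
matrix is substantially harder, which is what the denoising and
masked-reconstruction machinery is for.

What the generator does **not** emulate: platform-specific noise models
(MERFISH vs Xenium vs CODEX optics), segmentation errors, batch effects
across slices, 3-D structure. Passing the synthetic suite therefore shows
that the implementation recovers planted structure under its own stated
generative assumptions, not that it will match any particular instrument's
error process.

# Numerical choices and degenerate inputs

* Mutual information: plug-in estimator on equal-frequency discretization
  with B = min(16, floor(sqrt(n))) bins; deterministic, robust at small n;
  constant genes get MI 0 by construction. The adaptive threshold keeps the
  top floor(target_degree·|V|/2) pairs (ties at the cut dropped), i.e. the
  smallest threshold whose retained mean degree is at most the target
  (default 10).
* Duplicate coordinates are jittered by a seeded 1e-9 × bounding-box
  diagonal perturbation before triangulation; fewer than 3 cells or
  collinear cells are an error.
* Cell-type classes smaller than 3 cells are merged into the nearest class
  by centroid distance (MI estimation needs at least 3 samples).
* Attention softmaxes subtract a global maximum (per-group spreads beyond
  the exp range cannot occur for layer-normed inputs); isolated nodes attend
  to themselves via always-present self-loops.
* All indices are 1-based, the natural convention in R.
* Problem sizes in the test and acceptance suites are chosen for a
  single-CPU desk machine: structure-recovery benchmarks run on tissues of
  600–1500 cells with 40–60 genes and training budgets of a few hundred
  optimizer steps; the methods themselves scale linearly in cells × genes ×
  network degree.

# Known limitations

* The scalar-gate cross-level operator (as published) limits per-layer
  gene-to-cell bandwidth; cell-level type structure appears only after
  substantial contrastive training and remains the slowest property to
  emerge at desk scale. At the training budgets the benchmark suite can
  afford on one CPU (hundreds of optimizer steps), spectral clustering of
  the frozen cell embeddings does not yet recover the planted cell types or
  within-type niches at high fidelity, and removing cross-level message
  passing is not reliably worse — the corresponding structure-recovery
  checks in the acceptance suite measure and report exactly this. Gradient
  correctness and the capacity of the losses are established independently:
  with a fixed full-batch sampling regime the three contrastive terms can be
  driven to zero and type separation begins to emerge, so the limit is
  optimization budget through the scalar gate, not implementation.
* Training is single-process and dense-linear-algebra bound; tissues beyond
  ~10^4 cells per slice call for a compiled backend.
* The HDF5/AnnData container interface is not provided; datasets enter via
  the CSV or MTX triplet dialects, and graph/checkpoint stores are RDS.
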