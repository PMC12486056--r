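# spathgt — hierarchical graph-transformer embeddings for spatial omics

`spathgt` learns self-supervised cell and gene embeddings for single-cell
*spatial* transcriptomics and proteomics (MERFISH-, Xenium-, CODEX-style
data: an expression matrix plus 2-D coordinates per cell). It is built for
analysts who want microenvironment-aware representations — embeddings in
which a cell's identity reflects both its own transcriptional program and
its spatial neighbourhood — without a GPU or external pretrained weights.

## The model

A tissue is represented as a two-level graph

* **spatial cell graph** `G_c`: cells connected by Voronoi adjacency
  (Delaunay triangulation, long hull edges pruned);
* **gene co-expression networks** `G_g^t`, one per cell type `t`: genes
  connected when the mutual information of their denoised expression within
  that type exceeds a threshold (constant, or adaptive to a target mean
  degree); every cell carries its type's network.

The encoder stacks `L` layers; each runs neighbour-restricted multi-head
attention *within* each level and then *directional cross-level message
passing*

```
CMP(H_to, H_from) = ( <H_to Wq , H_from Wk> / d ) · H_to Wv
```

(row-wise inner product, so a scalar gate per row): genes receive their
parent cell's state, cells receive the pooled summary of their gene rows.
The final embeddings `Zc` (|C| × d) and `Zg` (|C||V| × d) feed a 3-layer GIN
decoder that reconstructs coordinates and expression. Pretraining combines a
spatially-aware InfoNCE contrastive loss (positives: same-type cells within
a radius; negatives: different-type cells within the radius, at cell–cell,
gene–gene and cell–gene level), masked auto-encoding of coordinates and
gene values, and an orthogonality penalty, balanced by a learnable scalar:

```
L = sigmoid(γ)·L_contrastive + (1 − sigmoid(γ))·L_mae + λ·L_ortho
```

Everything — including backpropagation — runs on an in-package autodiff
tape in plain R; gradients are verified against finite differences in the
test suite. A synthetic-tissue generator with planted cell types, spatial
niches, co-expression modules and dropout makes every stage testable
without external data.

## Worked example

```r
library(spathgt)

# a 400-cell tissue with 3 planted types, 3 spatial niches, 40% dropout
tissue <- generate_tissue(generator_config(n_cells = 400, n_genes = 40, seed = 7))
raw    <- expr_matrix(tissue$observed, layer = "raw")

hg <- build_hierarchical_graph(raw, as.matrix(tissue$cells[, c("x", "y")]),
                               labels = tissue$cells$type, seed = 7)
hg
#> <hier_graph> 398 cells (1163 spatial edges), 40 genes, 3 type networks

fit <- pretrain(hg, model_config(d = 64, L = 2, heads = 4, seed = 7),
                contrastive_config(),
                train_config(max_epochs = 4, patience = 3,
                             patch_cells = 128, seed = 7))
glance(fit)
#> # A tibble: 1 × 7
#>   epochs steps best_val_loss initial_train_loss final_train_loss   gamma contrastive_weight
#>    <int> <int>         <dbl>              <dbl>            <dbl>   <dbl>              <dbl>
#> 1      4    20          3.79               7.18             3.70 -0.0196              0.495
```

The total loss falls from 7.2 to 3.7 over four epochs (20 optimizer steps);
the learnable balance γ drifts slightly toward the masked-auto-encoding
term. Embeddings and downstream heads:

```r
st <- encode(hg, fit$model_cfg, fit$params)
keep <- match(hg$expression$cell_ids, tissue$cells$cell_id)

cluster_cells(st$cell_emb, tissue$cells$type[keep], method = "spectral")
#> # A tibble: 1 × 5
#>   task       metric_name  value split_descriptor       seed
#>   <chr>      <chr>        <dbl> <chr>                 <int>
#> 1 clustering NMI         0.0505 spectral, k=15, n=398     1

impute_genes(hg, fit, mask_fraction = 0.1, mode = "fine_tune", seed = 7)
#> # A tibble: 1 × 5
#>   task       metric_name value split_descriptor                             seed
#>   <chr>      <chr>       <dbl> <chr>                                       <int>
#> 1 imputation Pearson     0.558 fine_tune, mask_fraction=0.10, 1592 entries     7
```

The NMI row scores agreement between spectral clusters of the frozen cell
embeddings and the planted cell-type labels (1 = identical partitions; after
this short a pretraining budget the cell-level clustering signal is still
weak — see the vignette on why cell-level structure is the slowest property
to emerge). The imputation row is the pooled Pearson correlation between
decoder predictions and held-out masked expression values after decoder-only
fine-tuning — it clearly beats the per-gene-mean baseline (about 0.46 on
this tissue).

A command-line interface wraps the same pipeline
(`inst/cli/spathgt.R simulate | build-graphs | pretrain | embed | eval`);
every stage writes a JSON manifest with the resolved configuration, its
hash and the seeds, so any artifact can be reproduced from its manifest.

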