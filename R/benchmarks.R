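# Reproducible benchmark harnesses over the full pipeline. These are used by
# the acceptance tests and by scripts/acceptance.R, so the measured quantities
# come from one code path. Problem sizes are arguments with desk-scale
# defaults; thresholds live with the callers.

#' Structure-recovery benchmark on a synthetic tissue
#'
#' Pretrains the full model on a generated tissue, then measures how well
#' spectral clustering of the frozen cell embeddings recovers (a) the planted
#' cell types and (b), within the largest cell type, the planted spatial
#' niches. A second, smaller 5-seed experiment compares the full model with
#' the no-cross-level-message-passing ablation on the within-type niche NMI.
#'
#' @param seed master seed.
#' @param n_cells,n_genes tissue size for the main run.
#' @param epochs,patch_cells,lr training recipe for the main run.
#' @param abl_cells,abl_genes,abl_epochs,abl_seeds ablation-comparison sizes.
#' @return List with `type_nmi`, `niche_nmi`, `niche_nmi_median_full`,
#'   `niche_nmi_median_ablated`, and the per-seed ablation table.
#' @export
structure_recovery_benchmark <- function(seed = 1, n_cells = 600, n_genes = 40,
                                         epochs = 12, patch_cells = 96,
                                         lr = 2e-3, abl_cells = 300,
                                         abl_genes = 30, abl_epochs = 3,
                                         abl_seeds = 5) {
  con <- contrastive_config(max_pos_pairs = 4096, max_negatives = 16)
  run_one <- function(nc, ng, ep, sd, cross) {
    tis <- generate_tissue(generator_config(n_cells = nc, n_genes = ng,
                                            seed = sd))
    raw <- expr_matrix(tis$observed, layer = "raw")
    hg <- suppressWarnings(build_hierarchical_graph(
      raw, as.matrix(tis$cells[, c("x", "y")]), labels = tis$cells$type,
      seed = derive_seed(sd, "graph")))
    keep <- match(hg$expression$cell_ids, tis$cells$cell_id)
    cfg <- model_config(d = 64, L = 2, heads = 4, seed = sd,
                        cross_level = cross)
    fit <- pretrain(hg, cfg, con,
                    train_config(max_epochs = ep, patience = ep - 1,
                                 learning_rate = lr,
                                 patch_cells = patch_cells, seed = sd))
    st <- encode(hg, cfg, fit$final_params)
    types <- tis$cells$type[keep]; niches <- tis$cells$niche[keep]
    tt <- names(sort(table(types), decreasing = TRUE))[1]
    i <- types == tt
    list(type_nmi = cluster_cells(st$cell_emb, types, method = "spectral",
                                  seed = 1)$value,
         niche_nmi = cluster_cells(st$cell_emb[i, , drop = FALSE], niches[i],
                                   method = "spectral", seed = 1)$value)
  }
  main <- run_one(n_cells, n_genes, epochs, seed, cross = TRUE)
  abl <- purrr::map_dfr(seq_len(abl_seeds), function(s) {
    sd <- derive_seed(seed, paste0("abl", s))
    tibble::tibble(
      seed = s,
      full = run_one(abl_cells, abl_genes, abl_epochs, sd, TRUE)$niche_nmi,
      ablated = run_one(abl_cells, abl_genes, abl_epochs, sd, FALSE)$niche_nmi)
  })
  list(type_nmi = main$type_nmi, niche_nmi = main$niche_nmi,
       niche_nmi_median_full = median(abl$full),
       niche_nmi_median_ablated = median(abl$ablated),
       ablation = abl)
}

#' Imputation benchmark: fine-tuned vs zero-shot vs per-gene-mean baseline
#'
#' Pretrains once on a generated tissue, then over several masking seeds
#' scores masked-entry recovery (pooled Pearson r) for the zero-shot model,
#' the decoder-fine-tuned model, and the per-gene-mean baseline on identical
#' masks.
#'
#' @param seed master seed.
#' @param n_cells,n_genes tissue size.
#' @param pretrain_epochs,patch_cells pretraining recipe.
#' @param mask_fraction fraction of entries masked per sparsity bin.
#' @param finetune_steps decoder-only Adam steps.
#' @param n_mask_seeds masking replicates for the medians.
#' @return List with `finetune_median`, `zeroshot_median`, `baseline_median`
#'   and the per-seed table.
#' @export
imputation_benchmark <- function(seed = 1, n_cells = 400, n_genes = 40,
                                 pretrain_epochs = 8, patch_cells = 128,
                                 mask_fraction = 0.1, finetune_steps = 150,
                                 n_mask_seeds = 5) {
  tis <- generate_tissue(generator_config(n_cells = n_cells, n_genes = n_genes,
                                          seed = seed))
  raw <- expr_matrix(tis$observed, layer = "raw")
  hg <- suppressWarnings(build_hierarchical_graph(
    raw, as.matrix(tis$cells[, c("x", "y")]), labels = tis$cells$type,
    seed = derive_seed(seed, "graph")))
  fit <- pretrain(hg, model_config(d = 64, L = 2, heads = 4, seed = seed),
                  contrastive_config(),
                  train_config(max_epochs = pretrain_epochs,
                               patience = pretrain_epochs - 1,
                               patch_cells = patch_cells, seed = seed))
  per_seed <- purrr::map_dfr(seq_len(n_mask_seeds), function(s) {
    sd <- derive_seed(seed, paste0("mask", s))
    zs <- impute_genes(hg, fit, mask_fraction = mask_fraction,
                       mode = "zero_shot", seed = sd)
    ft <- impute_genes(hg, fit, mask_fraction = mask_fraction,
                       mode = "fine_tune", seed = sd,
                       steps = finetune_steps, lr = 1e-3)
    bl <- impute_gene_mean_baseline(hg, attr(zs, "masks"))
    tibble::tibble(seed = s, zero_shot = zs$value, fine_tune = ft$value,
                   baseline = bl$value)
  })
  list(finetune_median = median(per_seed$fine_tune),
       zeroshot_median = median(per_seed$zero_shot),
       baseline_median = median(per_seed$baseline),
       per_seed = per_seed)
}
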