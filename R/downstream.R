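# Downstream tasks on frozen embeddings: clustering (NMI), cell-type
# annotation (macro-F1), tissue-level classification (AUROC), and gene
# imputation (Pearson r), plus decoder-only fine-tuning for imputation.

task_result <- function(task, metric_name, value, split_descriptor, seed) {
  structure(tibble::tibble(task = task, metric_name = metric_name,
                           value = value, split_descriptor = split_descriptor,
                           seed = as.integer(seed)),
            class = c("task_result", "tbl_df", "tbl", "data.frame"))
}

#' Normalized mutual information between two labelings
#'
#' @param a,b label vectors of equal length.
#' @return NMI in [0, 1]; 1 for identical partitions.
#' @export
nmi_score <- function(a, b) {
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)), method = "nmi")
}

#' Macro-averaged F1
#'
#' Per-class F1 (0 when precision + recall is 0), averaged over the classes
#' present in the truth.
#'
#' @param truth,pred label vectors.
#' @return Macro F1 in [0, 1].
#' @export
macro_f1 <- function(truth, pred) {
  lev <- sort(unique(as.character(truth)))
  f1 <- vapply(lev, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Cluster cells on frozen embeddings
#'
#' Leiden (default) or spectral clustering on a kNN graph of the embedding
#' rows, scored by NMI against the provided labels. Works with any label set
#' — cell types, or planted niche labels restricted to one type, to probe
#' spatially-informed substructure.
#'
#' @param Z cells x d embedding matrix (e.g. `state$cell_emb`).
#' @param labels reference labels, one per row of `Z`.
#' @param method `"leiden"` or `"spectral"`.
#' @param k kNN graph degree.
#' @param resolution Leiden resolution.
#' @param n_clusters spectral cluster count (defaults to the number of
#'   distinct labels).
#' @param seed clustering seed.
#' @return A `task_result` tibble row (metric NMI) with the cluster
#'   assignment in attribute `"clusters"`.
#' @export
cluster_cells <- function(Z, labels, method = c("leiden", "spectral"), k = 15,
                          resolution = 1, n_clusters = NULL, seed = 1) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  n <- nrow(Z)
  stopifnot(length(labels) == n)
  k <- min(k, n - 1)
  nn <- FNN::get.knn(Z, k = k)
  el <- cbind(rep(seq_len(n), k), as.vector(nn$nn.index))
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  if (method == "leiden") {
    comm <- with_seed(seed, igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = resolution))
    cl <- as.integer(igraph::membership(comm))
  } else {
    A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
    deg <- Matrix::rowSums(A)
    Dm <- Matrix::Diagonal(x = 1 / sqrt(pmax(deg, 1e-12)))
    Lsym <- Matrix::Diagonal(n) - Dm %*% A %*% Dm
    kc <- n_clusters %||% length(unique(labels))
    ev <- eigen(as.matrix(Lsym), symmetric = TRUE)
    U <- ev$vectors[, n - seq_len(kc) + 1, drop = FALSE]
    U <- U / pmax(sqrt(rowSums(U^2)), 1e-12)
    cl <- with_seed(seed, stats::kmeans(U, centers = kc, nstart = 10)$cluster)
  }
  if (length(unique(cl)) == 1)
    warning("clustering found a single cluster; NMI may be 0", call. = FALSE)
  res <- task_result("clustering", "NMI", nmi_score(cl, labels),
                     sprintf("%s, k=%d, n=%d", method, k, n), seed)
  attr(res, "clusters") <- cl
  res
}

# stratified train index: ~frac of each class (singletons go to train)
stratified_split <- function(labels, frac, seed) {
  with_seed(seed, {
    idx <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
      if (length(ix) < 2) {
        warning("class with a single member kept in the training split",
                call. = FALSE)
        return(ix)
      }
      resample(ix, max(1, round(length(ix) * frac)))
    }))
    sort(idx)
  })
}

#' Annotate cells with an MLP head on frozen embeddings
#'
#' Stratified 80/20 split, a single-hidden-layer perceptron (softmax output)
#' on the frozen embeddings, macro-F1 on the held-out cells.
#'
#' @param Z cells x d embedding matrix.
#' @param labels cell-type labels (>= 2 classes).
#' @param split_seed seed for the split and the MLP initialization.
#' @param hidden hidden units.
#' @param max_iter optimizer iterations.
#' @return A `task_result` row (metric macroF1) with predictions in attribute
#'   `"predictions"`.
#' @export
annotate_cells <- function(Z, labels, split_seed = 1, hidden = 32,
                           max_iter = 200) {
  Z <- as.matrix(Z)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop_spathgt("need >= 2 classes to annotate")
  tr <- stratified_split(labels, 0.8, split_seed)
  te <- setdiff(seq_len(nrow(Z)), tr)
  if (length(te) == 0) stop_spathgt("no held-out cells; dataset too small")
  fit <- with_seed(split_seed,
    nnet::nnet(x = Z[tr, , drop = FALSE], y = nnet::class.ind(labels[tr]),
               size = hidden, softmax = TRUE, maxit = max_iter,
               decay = 5e-4, trace = FALSE, MaxNWts = 1e6))
  pr <- predict(fit, Z[te, , drop = FALSE])
  pred <- factor(colnames(pr)[max.col(pr)], levels = levels(labels))
  res <- task_result("annotation", "macroF1", macro_f1(labels[te], pred),
                     sprintf("stratified 80/20, n_test=%d", length(te)),
                     split_seed)
  attr(res, "predictions") <- pred
  res
}

#' Tissue-level classification from pooled cell embeddings
#'
#' Each tissue is represented by the mean of its cell embeddings; a
#' perceptron head is scored by AUROC under leave-one-tissue-out
#' cross-validation.
#'
#' @param Z cells x d embedding matrix pooled over all tissues.
#' @param tissue per-cell tissue identifier.
#' @param outcome per-cell binary class label (constant within tissue).
#' @param seed MLP seed.
#' @param hidden hidden units.
#' @return A `task_result` row (metric AUROC).
#' @export
classify_tissue <- function(Z, tissue, outcome, seed = 1, hidden = 8) {
  Z <- as.matrix(Z)
  tissue <- as.character(tissue)
  tabs <- tapply(as.character(outcome), tissue, function(v) unique(v))
  if (any(lengths(tabs) != 1)) stop_spathgt("outcome must be constant within a tissue")
  ids <- names(tabs)
  if (length(ids) < 4) stop_spathgt("need >= 4 tissues")
  y <- factor(unlist(tabs))
  if (nlevels(y) != 2) stop_spathgt("need exactly 2 outcome classes")
  if (any(table(y) < 2)) stop_spathgt("a class with a single tissue leaves AUROC undefined under cross-validation")
  M <- do.call(rbind, lapply(ids, function(t)
    colMeans(Z[tissue == t, , drop = FALSE])))
  scores <- numeric(length(ids))
  pos <- levels(y)[2]
  for (i in seq_along(ids)) {
    fit <- with_seed(derive_seed(seed, paste0("cv", i)),
      nnet::nnet(x = M[-i, , drop = FALSE], y = nnet::class.ind(y[-i]),
                 size = hidden, softmax = TRUE, maxit = 200, decay = 1e-3,
                 trace = FALSE, MaxNWts = 1e6))
    pr <- predict(fit, M[i, , drop = FALSE])
    scores[i] <- pr[1, pos]
  }
  auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = scores,
                                        levels = levels(y), direction = "<",
                                        quiet = TRUE)))
  task_result("tissue_classification", "AUROC", auc,
              sprintf("leave-one-tissue-out, %d tissues", length(ids)), seed)
}

# sparsity-stratified entry masks for imputation: quartile bins of per-gene
# zero fraction, mask_fraction of each bin's entries
imputation_masks <- function(hg, mask_fraction, seed) {
  X <- hg$expression$values
  nC <- nrow(X); nV <- ncol(X)
  zf <- colMeans(X == 0)
  bins <- cut(rank(zf, ties.method = "first"), breaks = 4, labels = FALSE)
  gm <- matrix(0, nC, nV)
  with_seed(seed, {
    for (b in 1:4) {
      genes <- which(bins == b)
      if (length(genes) == 0) { warning("empty sparsity bin ", b, "; skipped", call. = FALSE); next }
      entries <- as.vector(outer(seq_len(nC), (genes - 1) * nC, "+"))
      take <- resample(entries, max(1, round(length(entries) * mask_fraction)))
      gm[take] <- 1
    }
  })
  structure(list(cell_mask = rep(FALSE, nC), gene_mask = gm,
                 rates = c(cell_rate = 0, gene_rate = mask_fraction),
                 seed = as.integer(seed)),
            class = "mask_spec")
}

#' Impute masked gene expression
#'
#' Masks entries stratified by gene sparsity (quartiles of per-gene zero
#' fraction), encodes the masked tissue, and scores the decoder's predictions
#' at masked entries by Pearson correlation with the held-out truth.
#' `mode = "zero_shot"` uses the pretrained encoder + decoder as-is;
#' `mode = "fine_tune"` re-trains the expression decoder only (encoder
#' frozen) on the unmasked entries before scoring.
#'
#' @param hg a `hier_graph`.
#' @param fit a `spathgt_fit` (or checkpoint) compatible with `hg`'s genes.
#' @param mask_fraction fraction of entries masked per sparsity bin.
#' @param mode `"zero_shot"` or `"fine_tune"`.
#' @param seed masking / fine-tuning seed.
#' @param steps,lr fine-tuning schedule (Adam on decoder weights).
#' @return A `task_result` row (metric Pearson) with attributes
#'   `"predictions"` and `"truth"` (masked-entry vectors) and `"masks"`.
#' @export
impute_genes <- function(hg, fit, mask_fraction = 0.1,
                         mode = c("zero_shot", "fine_tune"), seed = 1,
                         steps = 200, lr = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(inherits(hg, "hier_graph"), inherits(fit, "spathgt_fit"))
  masks <- imputation_masks(hg, mask_fraction, seed)
  cfg <- fit$model_cfg
  params <- fit$params
  state <- encode(hg, cfg, params, masks = masks)
  nV <- n_genes(hg)
  flat_mask <- which(t(masks$gene_mask) == 1)
  truth <- as.vector(t(hg$expression$values))[flat_mask]

  if (mode == "fine_tune") {
    A_gene <- hg_cache(hg)$A_gene
    dec_names <- grep("^dec\\.gene\\.", names(params), value = TRUE)
    unmasked <- which(t(masks$gene_mask) == 0)
    target_un <- matrix(as.vector(t(hg$expression$values))[unmasked], ncol = 1)
    opt <- adam_init(params[dec_names])
    dp <- params[dec_names]
    for (s in seq_len(steps)) {
      tape <- ad_tape(record = TRUE)
      P <- c(param_handles(tape, dp, trainable = TRUE),
             param_handles(tape, params[setdiff(names(params), dec_names)],
                           trainable = FALSE))
      Zg <- ad_wrap(tape, state$gene_emb)
      xh <- gin_stack(P, "gene", Zg, A_gene)
      err <- ad_sub(ad_rows(xh, unmasked), target_un)
      loss <- ad_mean(ad_square(err))
      grads_by_id <- ad_backward(loss)
      grads <- lapply(P[dec_names], function(h) grads_by_id[[h$id]])
      upd <- adam_step(dp, grads, opt, lr, clip = 5)
      dp <- upd$params; opt <- upd$state
    }
    params[dec_names] <- dp
  }
  recon <- decode(hg, state, params, cfg)
  pred <- as.vector(t(recon$expression_hat))[flat_mask]
  r <- if (sd(pred) == 0 || sd(truth) == 0) {
    warning("constant predictions or truth; Pearson undefined, reported as 0",
            call. = FALSE)
    0
  } else cor(pred, truth)
  res <- task_result("imputation", "Pearson", r,
                     sprintf("%s, mask_fraction=%.2f, %d entries", mode,
                             mask_fraction, length(flat_mask)), seed)
  attr(res, "predictions") <- pred
  attr(res, "truth") <- truth
  attr(res, "masks") <- masks
  res
}

#' Per-gene-mean imputation baseline
#'
#' Predicts each masked entry by the mean of that gene's unmasked entries —
#' the reference any model-based imputation must beat.
#'
#' @param hg a `hier_graph`.
#' @param masks a `mask_spec` (e.g. from [impute_genes()]'s `"masks"`
#'   attribute, for a paired comparison).
#' @return A `task_result` row (metric Pearson) with attributes
#'   `"predictions"` and `"truth"`.
#' @export
impute_gene_mean_baseline <- function(hg, masks) {
  X <- hg$expression$values
  gm <- masks$gene_mask == 1
  mu <- vapply(seq_len(ncol(X)), function(v) {
    un <- X[!gm[, v], v]
    if (length(un) == 0) mean(X[, v]) else mean(un)
  }, numeric(1))
  pred_mat <- matrix(mu, nrow(X), ncol(X), byrow = TRUE)
  flat_mask <- which(t(gm))
  pred <- as.vector(t(pred_mat))[flat_mask]
  truth <- as.vector(t(X))[flat_mask]
  r <- if (sd(pred) == 0 || sd(truth) == 0) {
    warning("constant predictions or truth; Pearson undefined, reported as 0",
            call. = FALSE)
    0
  } else cor(pred, truth)
  res <- task_result("imputation", "Pearson", r, "per-gene-mean baseline", masks$seed)
  attr(res, "predictions") <- pred
  attr(res, "truth") <- truth
  res
}
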