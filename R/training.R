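# Pretraining: spatial patch batching, Adam, early stopping, checkpoints.

#' Training configuration
#'
#' @param max_epochs upper bound on epochs.
#' @param patience epochs without validation improvement before stopping
#'   (must be < `max_epochs`; `patience = 0` trains exactly one epoch).
#' @param learning_rate Adam learning rate.
#' @param patch_cells spatial batch size: each batch is a breadth-first
#'   neighbourhood of an anchor cell truncated at this many cells (>= 32 —
#'   smaller patches carry too little microenvironmental context).
#' @param optimizer only `"adam"` is provided.
#' @param seed master seed; all masking/subsampling seeds derive from it.
#' @param validation_fraction fraction of patches held out (patch-level
#'   split, keeping spatial context intact within each unit).
#' @param clip_norm global gradient-norm clip.
#' @param lambda orthogonality weight in the combined loss.
#' @param cell_mask_rate,gene_mask_rate masking rates for the MAE objective.
#' @return List of class `train_config`.
#' @export
train_config <- function(max_epochs = 20, patience = 3, learning_rate = 1e-3,
                         patch_cells = 512, optimizer = "adam", seed = 1,
                         validation_fraction = 0.1, clip_norm = 5,
                         lambda = 1e-3, cell_mask_rate = 0.1,
                         gene_mask_rate = 0.3) {
  if (patience >= max_epochs) stop_spathgt("patience must be < max_epochs")
  if (patch_cells < 32) stop_spathgt("patch_cells must be >= 32")
  if (optimizer != "adam") stop_spathgt("unsupported optimizer: ", optimizer)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 patch_cells = as.integer(patch_cells),
                 optimizer = optimizer, seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 clip_norm = clip_norm, lambda = lambda,
                 cell_mask_rate = cell_mask_rate,
                 gene_mask_rate = gene_mask_rate),
            class = "train_config")
}

#' Cut a tissue into spatial patches
#'
#' Seeded anchors are drawn from the not-yet-covered cells; each patch is the
#' anchor's breadth-first spatial neighbourhood truncated at `patch_cells`
#' cells, with the induced spatial edges and the gene networks of the types
#' present. Every cell appears in at least one patch; connected components
#' smaller than `patch_cells` come out as whole-component patches.
#'
#' @param hg a `hier_graph`.
#' @param patch_cells cells per patch.
#' @param seed anchor-sampling seed.
#' @return List of `hier_graph` patches, each with attribute `cell_index`
#'   giving original cell indices.
#' @export
make_patches <- function(hg, patch_cells, seed = 1) {
  n <- n_cells(hg)
  if (patch_cells >= n) {
    patch <- hg
    attr(patch, "cell_index") <- seq_len(n)
    return(list(patch))
  }
  e <- hg$cell_graph$edges
  nbr <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    nbr[[e[k, 1]]] <- c(nbr[[e[k, 1]]], e[k, 2])
    nbr[[e[k, 2]]] <- c(nbr[[e[k, 2]]], e[k, 1])
  }
  with_seed(seed, {
    order_ <- sample.int(n)
    covered <- logical(n)
    patches <- list()
    for (anchor in order_) {
      if (covered[anchor]) next
      visited <- logical(n)
      visited[anchor] <- TRUE
      cells <- anchor
      frontier <- anchor
      while (length(cells) < patch_cells && length(frontier) > 0) {
        nxt <- unique(unlist(nbr[frontier]))
        nxt <- nxt[!visited[nxt]]
        if (length(nxt) == 0) break
        take <- head(nxt, patch_cells - length(cells))
        visited[take] <- TRUE
        cells <- c(cells, take)
        frontier <- take
      }
      cells <- sort(cells)
      covered[cells] <- TRUE
      patches[[length(patches) + 1]] <- subset_hier_graph(hg, cells)
    }
    patches
  })
}

# induced sub-hier_graph on a sorted cell index vector
subset_hier_graph <- function(hg, cells) {
  map <- integer(n_cells(hg)); map[cells] <- seq_along(cells)
  e <- hg$cell_graph$edges
  keep <- map[e[, 1]] > 0 & map[e[, 2]] > 0
  sub_edges <- cbind(map[e[keep, 1]], map[e[keep, 2]])
  ct <- hg$cell_graph$cell_types[cells]
  cg <- structure(list(positions = hg$cell_graph$positions[cells, , drop = FALSE],
                       edges = matrix(as.integer(sub_edges), ncol = 2),
                       edge_lengths = hg$cell_graph$edge_lengths[keep],
                       cell_ids = hg$cell_graph$cell_ids[cells],
                       cell_types = ct,
                       # patches keep the parent tissue's coordinate frame so
                       # positional encodings agree across patches
                       pos_range = hg$cell_graph$pos_range),
                  class = "spatial_graph")
  expr <- expr_subset(hg$expression, cells = cells)
  out <- structure(list(cell_graph = cg,
                        gene_networks = hg$gene_networks[sort(unique(ct))],
                        expression = expr),
                   class = "hier_graph")
  attr(out, "cell_index") <- cells
  attr(out, "cache") <- new.env(parent = emptyenv())
  out
}

# ---- Adam ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, clip = 5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gn2 <- sum(vapply(grads, function(g) if (is.null(g)) 0 else sum(g^2), numeric(1)))
  scale <- if (clip > 0 && sqrt(gn2) > clip) clip / sqrt(gn2) else 1
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g * scale
    if (!is.null(dim(params[[nm]])) && is.null(dim(g))) dim(g) <- dim(params[[nm]])
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

# one full loss evaluation on a patch; returns handles (record=TRUE for training)
patch_loss <- function(tape, patch, model_cfg, con_cfg, P, masks, sets, samp_seed,
                       lambda) {
  enc <- encoder_forward(tape, patch, model_cfg, P, masks = masks)
  dec <- decoder_forward(tape, patch, model_cfg, P, enc$Zc, enc$Zg)
  con <- contrastive_core(tape, enc$Zc, enc$Zg, patch, sets, con_cfg, samp_seed)
  l_con <- ad_add(ad_add(con$l_cc, con$l_gg), con$l_cg)
  l_mae <- mae_core(tape, dec$pos_hat, dec$expr_hat, enc$init, masks)
  l_ortho <- ortho_core(tape, enc$Zc, enc$Zg)
  total <- total_core(l_con, l_mae, l_ortho, P$gamma, lambda)
  list(total = total, l_con = as.numeric(l_con$val),
       l_mae = as.numeric(l_mae$val), l_ortho = as.numeric(l_ortho$val))
}

#' Pretrain the model on a tissue
#'
#' Cuts the tissue into spatial patches, holds out a patch-level validation
#' split, and optimizes the combined objective (contrastive + masked
#' auto-encoding + orthogonality, balanced by the learnable scalar gamma)
#' with Adam. After each epoch the validation loss (fixed masks and sampling
#' seeds per validation patch, so epochs are comparable) decides early
#' stopping: training stops once `patience` epochs pass without improvement,
#' and the best-validation parameter snapshot is returned. If the loss turns
#' non-finite the run aborts, retaining the last good snapshot.
#'
#' @param hg a `hier_graph`.
#' @param model_cfg a [model_config()].
#' @param con_cfg a [contrastive_config()]; a `NULL` radius resolves to twice
#'   the median spatial edge length of `hg`.
#' @param tr_cfg a [train_config()].
#' @return Object of class `spathgt_fit`: list with `params` (best snapshot),
#'   `history` (tibble: step, epoch, l_contrastive, l_mae, l_ortho, gamma,
#'   total, split), `best_val_loss`, `epochs_run`, the three configs and a
#'   `manifest`.
#' @export
pretrain <- function(hg, model_cfg = model_config(),
                     con_cfg = contrastive_config(),
                     tr_cfg = train_config()) {
  stopifnot(inherits(hg, "hier_graph"))
  if (is.null(con_cfg$radius)) con_cfg$radius <- default_radius(hg$cell_graph)
  patches <- make_patches(hg, tr_cfg$patch_cells, seed = derive_seed(tr_cfg$seed, "patches"))
  np <- length(patches)
  n_val <- max(if (np > 1) 1L else 0L, floor(np * tr_cfg$validation_fraction))
  val_idx <- if (n_val > 0)
    with_seed(derive_seed(tr_cfg$seed, "valsplit"), sort(sample.int(np, n_val)))
  else integer(0)
  train_idx <- setdiff(seq_len(np), val_idx)
  if (length(train_idx) == 0) { train_idx <- val_idx; val_idx <- integer(0) }
  sets_by_patch <- lapply(patches, function(p)
    positive_negative_sets(p$cell_graph, cfg = con_cfg))

  params <- init_params(model_cfg)
  opt <- adam_init(params)
  best <- list(params = params, val = Inf)
  since_best <- 0L
  hist <- list()
  step <- 0L
  epochs_run <- 0L

  eval_val <- function(params) {
    if (length(val_idx) == 0) return(NA_real_)
    tot <- 0
    for (v in val_idx) {
      tape <- ad_tape(record = FALSE)
      P <- param_handles(tape, params, trainable = FALSE)
      masks <- make_masks(patches[[v]], tr_cfg$cell_mask_rate,
                          tr_cfg$gene_mask_rate,
                          seed = derive_seed(tr_cfg$seed, paste0("valmask", v)))
      pl <- patch_loss(tape, patches[[v]], model_cfg, con_cfg, P, masks,
                       sets_by_patch[[v]],
                       derive_seed(tr_cfg$seed, paste0("valsamp", v)),
                       tr_cfg$lambda)
      tot <- tot + as.numeric(pl$total$val)
    }
    tot / length(val_idx)
  }

  for (epoch in seq_len(tr_cfg$max_epochs)) {
    order_ <- with_seed(derive_seed(tr_cfg$seed, paste0("order", epoch)),
                        sample(train_idx))
    diverged <- FALSE
    for (b in order_) {
      step <- step + 1L
      tape <- ad_tape(record = TRUE)
      P <- param_handles(tape, params, trainable = TRUE)
      masks <- make_masks(patches[[b]], tr_cfg$cell_mask_rate,
                          tr_cfg$gene_mask_rate,
                          seed = derive_seed(tr_cfg$seed, paste0("mask", step)))
      pl <- patch_loss(tape, patches[[b]], model_cfg, con_cfg, P, masks,
                       sets_by_patch[[b]],
                       derive_seed(tr_cfg$seed, paste0("samp", step)),
                       tr_cfg$lambda)
      if (!is.finite(as.numeric(pl$total$val))) {
        warning("non-finite training loss at step ", step,
                "; aborting with last good checkpoint", call. = FALSE)
        diverged <- TRUE
        break
      }
      grads_by_id <- ad_backward(pl$total)
      grads <- lapply(P, function(h) grads_by_id[[h$id]])
      upd <- adam_step(params, grads, opt, tr_cfg$learning_rate,
                       clip = tr_cfg$clip_norm)
      params <- upd$params; opt <- upd$state
      hist[[length(hist) + 1]] <- tibble::tibble(
        step = step, epoch = epoch, l_contrastive = pl$l_con,
        l_mae = pl$l_mae, l_ortho = pl$l_ortho,
        gamma = as.numeric(params$gamma), total = as.numeric(pl$total$val),
        split = "train")
    }
    epochs_run <- epoch
    if (diverged) break
    vl <- eval_val(params)
    if (!is.na(vl)) {
      hist[[length(hist) + 1]] <- tibble::tibble(
        step = step, epoch = epoch, l_contrastive = NA_real_,
        l_mae = NA_real_, l_ortho = NA_real_,
        gamma = as.numeric(params$gamma), total = vl, split = "validation")
      if (vl < best$val - 1e-8) {
        best <- list(params = params, val = vl)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      if (since_best >= tr_cfg$patience) break
    } else {
      best <- list(params = params, val = NA_real_)
      if (tr_cfg$patience == 0 && epoch >= 1) break
    }
  }
  if (is.infinite(best$val)) best <- list(params = params, val = NA_real_)

  manifest <- list(model_config = unclass(model_cfg),
                   contrastive_config = unclass(con_cfg),
                   train_config = unclass(tr_cfg),
                   n_cells = n_cells(hg), n_genes = n_genes(hg),
                   n_patches = np, epochs_run = epochs_run)
  manifest$config_hash <- config_hash(manifest)
  structure(list(params = best$params, final_params = params,
                 best_val_loss = best$val, epochs_run = epochs_run,
                 history = dplyr::bind_rows(hist),
                 model_cfg = model_cfg, con_cfg = con_cfg, tr_cfg = tr_cfg,
                 manifest = manifest),
            class = "spathgt_fit")
}

#' @exportS3Method base::print
print.spathgt_fit <- function(x, ...) {
  cat(sprintf("<spathgt_fit> %d epoch(s), %d step(s); best val loss %.4g\n",
              x$epochs_run, sum(x$history$split == "train"), x$best_val_loss))
  invisible(x)
}

#' Save / load a checkpoint
#'
#' A checkpoint directory holds the parameter snapshot (`params.rds`) and a
#' JSON manifest (config hash, seeds, shapes). Loading restores a fit object
#' sufficient for [encode()], [decode()] and the downstream tasks.
#'
#' @param fit a `spathgt_fit`.
#' @param dir checkpoint directory (created if missing).
#' @return `save_checkpoint` returns `dir` invisibly; `load_checkpoint`
#'   returns a `spathgt_fit`.
#' @export
save_checkpoint <- function(fit, dir) {
  stopifnot(inherits(fit, "spathgt_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(fit[c("params", "final_params", "best_val_loss", "epochs_run",
                "history", "model_cfg", "con_cfg", "tr_cfg", "manifest")],
          file.path(dir, "params.rds"), compress = FALSE)
  shapes <- lapply(fit$params, function(p) dim(p) %||% length(p))
  jsonlite::write_json(list(manifest = fit$manifest, shapes = shapes),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  obj <- readRDS(file.path(dir, "params.rds"))
  structure(obj, class = "spathgt_fit")
}

#' Tidy a pretraining fit: the per-step loss history
#'
#' @param x a `spathgt_fit`.
#' @param ... unused.
#' @return The history tibble (step, epoch, loss components, gamma, total,
#'   split).
#' @export
tidy.spathgt_fit <- function(x, ...) x$history

#' One-row summary of a pretraining fit
#'
#' @param x a `spathgt_fit`.
#' @param ... unused.
#' @return Tibble: epochs run, steps, best validation loss, first/last
#'   training loss, final gamma weight.
#' @export
glance.spathgt_fit <- function(x, ...) {
  tr <- x$history[x$history$split == "train", ]
  tibble::tibble(epochs = x$epochs_run, steps = nrow(tr),
                 best_val_loss = x$best_val_loss,
                 initial_train_loss = tr$total[1],
                 final_train_loss = tr$total[nrow(tr)],
                 gamma = tr$gamma[nrow(tr)],
                 contrastive_weight = 1 / (1 + exp(-tr$gamma[nrow(tr)])))
}

#' Plot the loss history of a fit
#'
#' @param object a `spathgt_fit`.
#' @param ... unused.
#' @return A ggplot of total loss per step, coloured by split.
#' @export
autoplot.spathgt_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$step, y = .data$total,
                               colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(x = "optimizer step", y = "total loss") +
    ggplot2::theme_minimal()
}
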